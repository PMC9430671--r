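# Standard amino-acid residue masses (Da): residue = amino acid minus water.
.MONO_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)
.AVG_RESIDUE <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.WATER_MONO <- 18.010565
.WATER_AVG <- 18.01528
.PROTON <- 1.00728

#' Gel-filtration partition coefficient
#'
#' \deqn{K_{av} = (V_e - V_0) / (V_t - V_0)}
#'
#' @param ve Elution volume of the protein (mL).
#' @param v0 Column void volume (mL).
#' @param vt Total column volume (mL).
#' @return Kav in [0, 1]. Errors when \code{ve} lies outside
#'   \code{[v0, vt]} (protein outside the fractionation range).
#' @examples
#' kav(16.89, 7.2, 24)
#' @export
kav <- function(ve, v0, vt) {
  if (v0 >= vt) stop("v0 must be < vt")
  if (any(ve < v0 | ve > vt))
    stop("ve outside [v0, vt]: protein outside the fractionation range")
  (ve - v0) / (vt - v0)
}

#' The six gel-filtration protein standards
#'
#' Thyroglobulin (670 kDa, Rs 8.6 nm), gamma-globulin (158 kDa, 5.1 nm),
#' conalbumin (75 kDa, 3.72 nm), ovalbumin (44 kDa, 2.73 nm), myoglobin
#' (17 kDa, 1.91 nm) and vitamin B12 (1.35 kDa, 0.85 nm). Elution volumes
#' are column-specific and must be supplied by the user.
#'
#' @param ve_ml Optional numeric vector of six elution volumes (mL).
#' @return \code{data.frame} with columns \code{name}, \code{mass_kda},
#'   \code{rs_nm} and (when given) \code{ve_ml}.
#' @export
gfStandards <- function(ve_ml = NULL) {
  df <- data.frame(
    name = c("thyroglobulin", "gamma-globulin", "conalbumin", "ovalbumin",
             "myoglobin", "vitamin B12"),
    mass_kda = c(670, 158, 75, 44, 17, 1.35),
    rs_nm = c(8.6, 5.1, 3.72, 2.73, 1.91, 0.85))
  if (!is.null(ve_ml)) {
    stopifnot(length(ve_ml) == nrow(df))
    df$ve_ml <- ve_ml
  }
  df
}

#' Read a gel-filtration standards table
#'
#' @param tsv TSV with header columns \code{name}, \code{mass_kda},
#'   \code{rs_nm}, \code{ve_ml}.
#' @return \code{data.frame}.
#' @export
readGfStandards <- function(tsv) {
  df <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  need <- c("name", "mass_kda", "rs_nm", "ve_ml")
  if (!all(need %in% colnames(df)))
    stop("standards table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Calibrate a gel-filtration column from protein standards
#'
#' Two linearised least-squares fits: \code{log10(mass_kda) ~ Kav} for mass
#' and \code{sqrt(-ln Kav) ~ rs_nm} for the Stokes radius
#' (Laurent-Killander form). Standards eluting outside \code{[v0, vt]} are
#' excluded with a warning; standards at \code{Kav = 0} cannot enter the
#' Stokes-radius fit (its transform diverges) and are dropped from that fit
#' only.
#'
#' @param standards \code{data.frame} with columns \code{mass_kda},
#'   \code{rs_nm}, \code{ve_ml} (see \code{\link{gfStandards}}).
#' @param v0,vt Void and total column volumes (mL).
#' @return A \code{\link{CalibrationCurve}}.
#' @export
gfCalibrate <- function(standards, v0, vt) {
  ok <- standards$ve_ml >= v0 & standards$ve_ml <= vt
  if (any(!ok)) {
    warning(sum(!ok), " standard(s) outside [v0, vt] excluded: ",
            paste(standards$name[!ok], collapse = ", "))
    standards <- standards[ok, , drop = FALSE]
  }
  if (nrow(standards) < 3L)
    stop("at least 3 usable standards required")
  k <- kav(standards$ve_ml, v0, vt)
  r2_of <- function(fit, y) {
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot == 0) return(1)
    1 - sum(stats::residuals(fit)^2) / ss_tot
  }
  ym <- log10(standards$mass_kda)
  fit_m <- stats::lm(ym ~ k)
  r2_m <- r2_of(fit_m, ym)
  ok_rs <- k > 0 & k < 1  # -ln Kav defined and positive
  if (sum(ok_rs) >= 3L) {
    y <- sqrt(-log(k[ok_rs]))
    fit_r <- stats::lm(y ~ standards$rs_nm[ok_rs])
    rs_fit <- c(slope = unname(stats::coef(fit_r)[2]),
                intercept = unname(stats::coef(fit_r)[1]))
    r2_r <- r2_of(fit_r, y)
  } else {
    rs_fit <- c(slope = NA_real_, intercept = NA_real_)
    r2_r <- NA_real_
  }
  new("CalibrationCurve", v0 = v0, vt = vt,
      mass_fit = c(slope = unname(stats::coef(fit_m)[2]),
                   intercept = unname(stats::coef(fit_m)[1])),
      rs_fit = rs_fit, r2_mass = r2_m, r2_rs = r2_r,
      n_standards = nrow(standards))
}

#' Estimate a molecular mass from an elution volume
#'
#' Inverse of the fitted linearisation:
#' \code{mass = 10^(slope * Kav + intercept)}.
#'
#' @param ve Elution volume (mL), inside \code{[v0, vt]} of the curve.
#' @param curve A \code{\link{CalibrationCurve}}.
#' @return Apparent molecular mass (kDa).
#' @export
estimateMass <- function(ve, curve) {
  k <- kav(ve, curve@v0, curve@vt)
  10^(curve@mass_fit[["slope"]] * k + curve@mass_fit[["intercept"]])
}

#' Estimate a Stokes radius from an elution volume
#'
#' Inverse of the Laurent-Killander linearisation:
#' \code{Rs = (sqrt(-ln Kav) - intercept) / slope}.
#'
#' @inheritParams estimateMass
#' @return Apparent Stokes radius (nm).
#' @export
estimateRs <- function(ve, curve) {
  k <- kav(ve, curve@v0, curve@vt)
  if (k <= 0 || k >= 1) stop("Kav must be in (0, 1) for the Rs fit")
  (sqrt(-log(k)) - curve@rs_fit[["intercept"]]) / curve@rs_fit[["slope"]]
}

#' Molecular mass of a protein sequence
#'
#' Sum of standard residue masses plus one water.
#'
#' @param protein Protein sequence (standard one-letter residues).
#' @param kind \code{"monoisotopic"} (default) or \code{"average"}.
#' @return Mass in Da.
#' @examples
#' sequenceMass("G")   # 75.03203
#' sequenceMass("GG")  # 132.05349
#' @export
sequenceMass <- function(protein, kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  protein <- toupper(as.character(protein))
  if (nchar(protein) == 0) stop("empty sequence")
  chars <- strsplit(protein, "")[[1L]]
  tab <- if (kind == "monoisotopic") .MONO_RESIDUE else .AVG_RESIDUE
  m <- tab[chars]
  if (anyNA(m))
    stop("unknown residue '", chars[which(is.na(m))[1L]], "' at position ",
         which(is.na(m))[1L])
  sum(m) + if (kind == "monoisotopic") .WATER_MONO else .WATER_AVG
}

#' Absolute deviation between experimental and theoretical mass
#'
#' @param experimental,theoretical Masses (Da), both positive.
#' @return \code{abs(experimental - theoretical)} in Da.
#' @examples
#' massDeviation(34063.70, 34064.28)  # 0.58
#' @export
massDeviation <- function(experimental, theoretical) {
  if (experimental <= 0 || theoretical <= 0)
    stop("masses must be positive")
  abs(experimental - theoretical)
}

#' Molar extinction coefficient at 280 nm
#'
#' Gill-von Hippel convention: 5500 per Trp, 1490 per Tyr, and, when
#' cystines are assumed, 125 per disulfide pair (\code{floor(nC / 2)}).
#'
#' @param protein Protein sequence.
#' @param cystines Assume all Cys pair into cystines (default \code{FALSE}).
#' @return Extinction coefficient in 1/(M cm).
#' @examples
#' extinctionCoefficient("W")    # 5500
#' extinctionCoefficient("WYY")  # 8480
#' @export
extinctionCoefficient <- function(protein, cystines = FALSE) {
  chars <- strsplit(toupper(as.character(protein)), "")[[1L]]
  eps <- sum(chars == "W") * 5500 + sum(chars == "Y") * 1490
  if (cystines) eps <- eps + (sum(chars == "C") %/% 2L) * 125
  eps
}

#' Neutral mass from a charge-state series
#'
#' Each electrospray peak at \code{mz} with charge \code{z} implies a
#' neutral mass \code{z * mz - z * 1.00728} (proton mass 1.00728 Da); the
#' mean and standard deviation across the series are returned (sd 0 for a
#' single peak).
#'
#' @param mz Numeric vector of peak m/z values.
#' @param z Integer vector of charges (same length, all > 0).
#' @return List with \code{mass} (Da), \code{sd}, \code{n},
#'   \code{per_peak}.
#' @examples
#' massFromCsd(4412.457, 20)$mass  # 88229
#' @export
massFromCsd <- function(mz, z) {
  if (length(mz) == 0) stop("at least one peak required")
  if (length(mz) != length(z)) stop("mz and z must have equal length")
  z <- as.integer(z)
  if (any(z <= 0)) stop("charges must be positive")
  masses <- z * mz - z * .PROTON
  list(mass = mean(masses),
       sd = if (length(masses) > 1L) stats::sd(masses) else 0,
       n = length(masses), per_peak = masses)
}

#' Predicted mass of an (a FLP, b CTP) complex
#'
#' @param a,b Non-negative subunit counts, not both zero.
#' @param m_flp,m_ctp Subunit masses (kDa).
#' @return \code{a * m_flp + b * m_ctp} (kDa).
#' @examples
#' complexMass(1, 5, 34.1, 10.8)  # 88.1
#' @export
complexMass <- function(a, b, m_flp, m_ctp) {
  if (any(a < 0) || any(b < 0)) stop("counts must be non-negative")
  if (any(a == 0 & b == 0)) stop("composition (0, 0) is not a complex")
  a * m_flp + b * m_ctp
}

#' Best integer stoichiometry for an observed complex mass
#'
#' Exhaustively enumerates compositions \code{0 <= a <= a_max},
#' \code{0 <= b <= b_max} (excluding (0, 0)) and minimises the absolute
#' deviation of \code{a * m_flp + b * m_ctp} from the observed mass. Ties
#' break by smaller a, then smaller b. The default bounds (3, 10) cover all
#' compositions of practical interest for FLP/CTP heteromultimers.
#'
#' @param observed Observed complex mass (kDa), e.g. from native MS.
#' @param m_flp,m_ctp Subunit masses (kDa).
#' @param a_max,b_max Enumeration bounds (default 3 and 10).
#' @return A \code{\link{StoichiometryFit}}.
#' @examples
#' fit <- bestStoichiometry(88.229, 34.1, 10.8)
#' bestComposition(fit)  # 1 FLP : 5 CTP
#' @export
bestStoichiometry <- function(observed, m_flp, m_ctp, a_max = 3L,
                              b_max = 10L) {
  if (observed <= 0) stop("observed mass must be positive")
  a_max <- as.integer(a_max); b_max <- as.integer(b_max)
  if (a_max < 1L || b_max < 1L) stop("bounds must be at least (1, 1)")
  grid <- expand.grid(a = 0:a_max, b = 0:b_max)
  grid <- grid[grid$a + grid$b > 0, , drop = FALSE]
  grid$predicted <- grid$a * m_flp + grid$b * m_ctp
  grid$residual <- grid$predicted - observed
  grid <- grid[order(abs(grid$residual), grid$a, grid$b), , drop = FALSE]
  rownames(grid) <- NULL
  new("StoichiometryFit", m_flp = m_flp, m_ctp = m_ctp,
      observed = observed, a_max = a_max, b_max = b_max,
      best = c(grid$a[1L], grid$b[1L]), predicted = grid$predicted[1L],
      residual = grid$residual[1L], table = grid)
}
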