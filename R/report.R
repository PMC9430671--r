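# round half-up at `digits` decimals (printed-percentage convention;
# base round() is half-even)
.roundHalfUp <- function(x, digits = 1L) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Per-genus summary of a screen
#'
#' One row per host genus present in the cohort: the number of genes in the
#' initial (full) sample, the number retained after the four filters, and
#' the five-number summary of the retained TIRs with Tukey outliers (values
#' beyond 1.5 IQR of the quartiles) listed separately, ready for box-plot
#' rendering.
#'
#' @param screen A \code{\link{ScreenResult}}.
#' @param cohort The screened \code{\link{LysinCohort}}.
#' @return \code{data.frame} with columns \code{genus}, \code{n_full},
#'   \code{n_filtered}, \code{tir_min}, \code{tir_q1}, \code{tir_median},
#'   \code{tir_q3}, \code{tir_max} (NA when nothing retained) and a list
#'   column \code{outliers}.
#' @export
summarizeByGenus <- function(screen, cohort) {
  calls <- screenCalls(screen)
  genus <- hostGenus(cohort)
  stopifnot(all(calls$gene_id %in% names(genus)))
  out <- lapply(sort(unique(unname(genus))), function(g) {
    ids <- names(genus)[genus == g]
    sub <- calls[calls$gene_id %in% ids, , drop = FALSE]
    ret <- sub$tir[sub$status == "retained"]
    if (length(ret)) {
      q <- stats::quantile(ret, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      iqr <- q[4] - q[2]
      outl <- ret[ret < q[2] - 1.5 * iqr | ret > q[4] + 1.5 * iqr]
    } else {
      q <- rep(NA_real_, 5)
      outl <- numeric(0)
    }
    data.frame(genus = g, n_full = length(ids), n_filtered = length(ret),
               tir_min = q[1], tir_q1 = q[2], tir_median = q[3],
               tir_q3 = q[4], tir_max = q[5],
               outliers = I(list(outl)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @describeIn screenFraction From a \code{ScreenResult}.
#' @export
setMethod("screenFraction", signature(x = "ScreenResult",
                                      n_total = "missing"),
  function(x, n_total) {
    s <- screenSummary(x)
    if (s$n_total == 0) return(NA_real_)
    .roundHalfUp(100 * s$n_retained / s$n_total, 1L)
  })

#' @describeIn screenFraction From retained and total counts.
#' @export
setMethod("screenFraction", signature(x = "numeric", n_total = "numeric"),
  function(x, n_total) {
    if (n_total == 0) return(NA_real_)
    .roundHalfUp(100 * x / n_total, 1L)
  })

#' Write the per-genus summary as box-plot-ready TSV
#'
#' The list column of outliers is serialised as a comma-separated field.
#'
#' @param summary Output of \code{\link{summarizeByGenus}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGenusSummary <- function(summary, path) {
  flat <- summary
  flat$outliers <- vapply(summary$outliers, function(v)
    paste(signif(v, 6), collapse = ","), character(1))
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
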