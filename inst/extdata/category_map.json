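{
  "PF01510": "catalytic",
  "PF01520": "catalytic",
  "PF05382": "catalytic",
  "PF05257": "catalytic",
  "PF01183": "catalytic",
  "PF00959": "catalytic",
  "PF01832": "catalytic",
  "PF01551": "catalytic",
  "PF08460": "cwbd",
  "PF01476": "cwbd",
  "PF08230": "cwbd",
  "PF01473": "cwbd",
  "PF03906": "tail",
  "PF04865": "tail",
  "PF05100": "tail",
  "PF05939": "tail",
  "PF06605": "tail",
  "PF04860": "other"
}
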