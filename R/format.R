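# Display rounding used by the text reports:
#  - probabilities: 4 decimals, trailing zeros trimmed ("0.143", "0.4665")
#  - percentages:   2 decimals, trailing zeros trimmed ("54.75", "95", "90")
#  - point estimate: nearest whole percent ("86")

fmt_prob <- function(p) {
  s <- sprintf("%.4f", p)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

fmt_pct <- function(p) {
  s <- sprintf("%.2f", 100 * p)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

fmt_pct_whole <- function(p) {
  sprintf("%d", as.integer(round(100 * p)))
}
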