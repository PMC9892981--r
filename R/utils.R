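# Presentation-layer rounding: half away from zero (so 0.5 -> 1, -0.5 -> -1),
# unlike base round()'s round-half-even. Scoring itself never rounds.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# "x.xx (y.yy)" mean (SD) cell
fmt_mean_sd <- function(x, digits = 2) {
  sprintf("%.*f (%.*f)", digits, round_half_up(mean(x), digits),
          digits, round_half_up(stats::sd(x), digits))
}

# "n (p%)" cell with the percentage to one decimal
fmt_n_pct <- function(n, total, digits = 1) {
  sprintf("%d (%.*f)", as.integer(n), digits,
          round_half_up(100 * n / total, digits))
}

# p-values to 2 decimals with the leading zero dropped (".05" style);
# values that would print as ".00" are shown as "<.01"
fmt_p <- function(p) {
  out <- sprintf("%.2f", round_half_up(p, 2))
  out <- sub("^0", "", out)
  out[out == ".00"] <- "<.01"
  out[p >= 0.995] <- "1.00"
  out
}
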