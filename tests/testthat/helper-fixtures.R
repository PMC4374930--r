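# small builders shared across test files

toy_records <- function() {
  data.frame(
    category = c("soil", "marine", "troposphere"),
    d15N_bulk = c(-12.3, 6.1, 6.55),
    d18O = c(30.2, 47.0, 44.4),
    concentration_ppb = c(900, NA, NA),
    saturation_pct = c(NA, 250, NA),
    depth_m = c(NA, 20, NA),
    is_emitted = c(FALSE, FALSE, NA),
    site = c("plot A", "station B", "flask C"),
    reference = c("ref1", "ref2", "ref3")
  )
}

write_toy_csv <- function(df = toy_records(), path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# independent closed-form 2x2 eigen oracle (quadratic formula, no eigen())
eigen2x2_oracle <- function(sx, sy, r) {
  cv <- r * sx * sy
  tr <- sx^2 + sy^2
  det <- sx^2 * sy^2 - cv^2
  disc <- sqrt(tr^2 - 4 * det)
  lam1 <- (tr + disc) / 2
  lam2 <- (tr - disc) / 2
  theta <- 0.5 * atan2(2 * cv, sx^2 - sy^2)
  if (theta < 0) theta <- theta + pi
  list(a = sqrt(lam1), b = sqrt(lam2), theta = theta)
}

# a well-separated 3-source, 2-tracer recovery problem
recovery_sources <- function() {
  list(means = rbind(soil = c(-20, 30), freshwater = c(0, 45), marine = c(12, 60)),
       sds = matrix(2, 3, 2))
}
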