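# Shared fixtures: small geometries, plans, smooth random fields and film
# strip tables, all generated in code under fixed seeds.

tiny_geometry <- function(n = c(9, 9, 9), spacing = c(2, 2, 2),
                          origin = c(92, 92, 92)) {
  grid_geometry(origin, spacing, n)
}

single_shot_plan <- function(collimator = 18, iso = c(100, 100, 100),
                             plugs = list(), weight = 1) {
  plan_spec(list(shot_spec(iso, collimator, weight, plugs)),
            prescription_dose = 8, prescription_isodose = 0.5)
}

# smooth zero-mean random field with unit SD, scaled by amp
smooth_field <- function(seed, n = 21, spacing = 1, amp = 1, fwhm = 6) {
  set.seed(seed)
  a <- array(stats::rnorm(prod(rep(n, 3))), dim = rep(n, 3))
  a <- plugdose:::gaussian_blur(a, rep(spacing, 3), fwhm)
  (a - mean(a)) / stats::sd(a) * amp
}

# a correlated reference / evaluated dose pair on a 1 mm grid, emulating a
# measurement with smooth systematic deviation plus smooth noise
correlated_pair <- function(seed, n = 21) {
  g <- grid_geometry(c(90, 90, 90), rep(1, 3), rep(n, 3))
  ref <- smooth_field(seed, n = n, amp = 2) + 5
  ev <- ref * (1 + smooth_field(seed + 1000, n = n, amp = 0.02)) +
    smooth_field(seed + 2000, n = n, amp = 0.05)
  list(calculated = dose_grid(ref, g), measured = dose_grid(ev, g),
       geometry = g)
}

# calibration strips sampled from a film response
film_strips <- function(response = film_response(),
                        doses = seq(0, 10, length.out = 11)) {
  strips <- data.frame(dose_gy = doses)
  strips$od_r <- response$channels$red$od_of_dose(doses)
  strips$od_g <- response$channels$green$od_of_dose(doses)
  strips$od_b <- response$channels$blue$od_of_dose(doses)
  strips
}

# two-sided Wald-Wolfowitz runs test p-value on residual signs
runs_test_p <- function(res) {
  s <- sign(res)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0) return(0)
  runs <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / n + 1
  sigma <- sqrt(2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1)))
  if (sigma == 0) return(1)
  2 * stats::pnorm(-abs((runs - mu) / sigma))
}

# independent nonlinear exponential-decay oracle for R2 fitting
nls_r2_oracle <- function(signal, te_ms, start_r2 = 10, start_s0 = NULL) {
  te_s <- te_ms / 1000
  if (is.null(start_s0)) start_s0 <- max(signal)
  fit <- stats::nls(signal ~ A * exp(-te_s * R),
                    start = list(A = start_s0, R = start_r2),
                    algorithm = "port", lower = c(A = 0, R = 0),
                    control = stats::nls.control(maxiter = 200,
                                                 warnOnly = TRUE))
  stats::coef(fit)[["R"]]
}
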