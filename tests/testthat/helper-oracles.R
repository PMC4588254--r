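# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use different code paths from the package: ANOVA
# mean squares via stats::lm/anova, kappa via explicit count loops, and
# projections via direct trigonometry.

# ICC(2,1) from a subjects x raters matrix via a fitted two-way ANOVA.
oracle_icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n)))
  tab <- stats::anova(stats::lm(y ~ subject + rater, data = df))
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Fleiss' kappa by explicit counting (no matrix algebra shared with the
# package implementation).
oracle_fleiss <- function(m) {
  n <- nrow(m); k <- ncol(m)
  cats <- unique(as.vector(m))
  agree <- 0
  for (i in seq_len(n)) {
    s <- 0
    for (cat_ in cats) {
      nij <- sum(m[i, ] == cat_)
      s <- s + nij * (nij - 1)
    }
    agree <- agree + s / (k * (k - 1))
  }
  pbar <- agree / n
  pe <- 0
  for (cat_ in cats) {
    pj <- sum(m == cat_) / (n * k)
    pe <- pe + pj^2
  }
  (pbar - pe) / (1 - pe)
}

# Cohen's kappa for two raters by explicit counting.
oracle_cohen <- function(r1, r2) {
  n <- length(r1)
  cats <- unique(c(r1, r2))
  po <- sum(r1 == r2) / n
  pe <- 0
  for (cat_ in cats) {
    pe <- pe + (sum(r1 == cat_) / n) * (sum(r2 == cat_) / n)
  }
  (po - pe) / (1 - pe)
}

# Direct trigonometric AP projection of one 3D point (u, v) for tilt t deg.
oracle_ap_project <- function(p, tilt_deg) {
  t <- tilt_deg * pi / 180
  c(u = p[1], v = p[2] * sin(t) - p[3] * cos(t))
}

# Random categorical ratings matrix.
random_ratings <- function(n, k, categories = c("a", "b", "c")) {
  matrix(sample(categories, n * k, replace = TRUE), n, k)
}

# Render a sheet for a given single displacement of the default template.
displaced_sheet <- function(..., subject_id = "sub", mm_per_px = 0.5,
                            template = default_template(),
                            views = default_views()) {
  spec <- displacement_spec(...)
  render_sheets(displace(template, spec), subject_id = subject_id,
    views = views, mm_per_px = mm_per_px)
}
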