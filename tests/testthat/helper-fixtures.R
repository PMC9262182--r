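# Shared fixtures and independent brute-force oracles.
# The oracles deliberately use scalar loops / first principles so they stay
# independent of the vectorised implementation they check.

# A compact phantom spec that keeps unit tests fast.
small_spec <- function(...) {
  args <- list(grid_shape = c(40, 40, 30),
               voxel_spacing = c(2, 2, 2.5),
               lung_centers = rbind(c(12, 20, 15), c(28, 20, 15)),
               lung_semiaxes = rbind(c(6, 11, 11), c(6, 11, 11)))
  dots <- list(...)
  do.call(phantom_spec, c(args[setdiff(names(args), names(dots))], dots))
}

# Random tiny volume/mask pair (grid <= 5x5x5, labels 0/1/2, >=1 per side).
random_tiny_fixture <- function() {
  d <- sample(2:5, 3, replace = TRUE)
  vals <- array(round(stats::runif(prod(d), -1024, 100)), d)
  memb <- array(sample(0:2, prod(d), replace = TRUE), d)
  if (!any(memb == 1)) memb[sample(length(memb), 1)] <- 1L
  if (!any(memb == 2)) memb[sample(which(memb != 2), 1)] <- 2L
  list(volume = density_volume(vals, spacing = stats::runif(3, 0.5, 3)),
       mask = lung_mask(array(as.integer(memb), d)))
}

# Brute-force densitometry by scalar loops over every voxel.
bf_mean <- function(vals, memb, labels) {
  tot <- 0; n <- 0
  for (i in seq_along(vals))
    if (memb[i] %in% labels) { tot <- tot + vals[i]; n <- n + 1 }
  tot / n
}
bf_count <- function(memb, labels) {
  n <- 0
  for (i in seq_along(memb)) if (memb[i] %in% labels) n <- n + 1
  n
}
bf_fraction <- function(vals, memb, labels, thr, dir) {
  n <- 0; hit <- 0
  for (i in seq_along(vals)) {
    if (!(memb[i] %in% labels)) next
    n <- n + 1
    if (dir == "below" && vals[i] < thr) hit <- hit + 1
    if (dir == "above" && vals[i] > thr) hit <- hit + 1
  }
  100 * hit / n
}

# Brute-force AUC: loop over every (case, control) pair, ties 0.5.
bf_auc <- function(cases, controls) {
  s <- 0
  for (a in cases) for (b in controls)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(cases) * length(controls))
}

# Trapezoidal area under the empirical ROC curve (independent route).
bf_auc_trapezoid <- function(cases, controls) {
  thr <- sort(unique(c(cases, controls, Inf)), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(cases >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(controls >= t), numeric(1))
  sens <- c(0, sens, 1); fpr <- c(0, fpr, 1)
  sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

# Exhaustive Youden scan with the package's tie-break conventions
# (rule: positive when score >= cutoff; ties -> higher specificity,
# then higher cutoff), written as a direct scan for the oracle.
bf_youden <- function(cases, controls) {
  best <- NULL
  for (cutoff in sort(unique(c(cases, controls)))) {
    sens <- 100 * mean(cases >= cutoff)
    spec <- 100 * mean(controls < cutoff)
    j <- sens + spec
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec + 1e-12) ||
        (abs(j - best$j) <= 1e-12 && abs(spec - best$spec) <= 1e-12 &&
         cutoff > best$cutoff))
      best <- list(cutoff = cutoff, j = j, sens = sens, spec = spec)
  }
  best
}

# Two-group score table in the cohort layout expected by roc_analysis().
roc_table <- function(cases, controls) {
  data.frame(group = factor(rep(c("BO", "control"),
                                c(length(cases), length(controls))),
                            levels = c("control", "BO")),
             score = c(cases, controls))
}

# Quiet wrapper: phantom generation legitimately warns when Gaussian noise
# tails cross the HU plausibility floor; tests that are not about the
# warning use this.
quiet_phantom <- function(spec) suppressWarnings(generate_phantom(spec))
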