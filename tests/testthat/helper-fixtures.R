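# Shared fixtures, built once per test run.

.fixtures <- new.env()

# The standard 48^3 template phantom (deterministic).
stdPhantom <- function() {
  if (is.null(.fixtures$phantom))
    .fixtures$phantom <- buildTemplatePhantom(phantomSpec())
  .fixtures$phantom
}

# Atrophy spec with a single uniform rate, no variability, no nuisance terms.
uniformAtrophy <- function(rate) {
  atrophySpec(
    rateMean = matrix(rate, 2, 2,
                      dimnames = list(c("case", "control"), c("GM", "WM"))),
    rateSd = matrix(0, 2, 2,
                    dimnames = list(c("case", "control"), c("GM", "WM"))),
    sulcalExcess = 1, lesionProb = 0, scannerOffset = 0)
}

caseRecord <- function(interval = 1, lesion = FALSE) {
  list(id = "P001", group = "case", scanner = "A",
       interval_years = interval, lesion = lesion)
}

# A noiseless phantom spec (no noise, no scanner bias).
cleanSpec <- function(...) phantomSpec(noiseSd = 0, scannerBias = 0, ...)

# Smoothed random multi-subject stack of JD-like maps on a small grid.
jdNoiseStack <- function(n, dims = c(8, 8, 8), sd = 0.02, fwhm = 2,
                         seed = 1) {
  set.seed(seed)
  stack <- array(0, c(dims, n))
  for (i in seq_len(n)) {
    m <- array(1 + rnorm(prod(dims), 0, sd), dims)
    stack[, , , i] <- smoothVolume(m, fwhm, spacing = c(1, 1, 1))
  }
  stack
}

# Brute-force hierarchical partitioning: average incremental R^2 over all
# explicit predictor orderings (independent oracle for the subset-weighting
# implementation).
partitionByOrderings <- function(y, predictors) {
  k <- ncol(predictors)
  r2 <- function(cols) {
    if (length(cols) == 0) return(0)
    X <- model.matrix(~ ., predictors[, cols, drop = FALSE])
    f <- lm.fit(X, y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  perms <- gtoolsPerms(k)
  I <- numeric(k)
  for (p in seq_len(nrow(perms))) {
    sofar <- integer(0)
    for (pos in seq_len(k)) {
      j <- perms[p, pos]
      I[j] <- I[j] + r2(c(sofar, j)) - r2(sofar)
      sofar <- c(sofar, j)
    }
  }
  I / nrow(perms)
}

# all permutations of 1:k (k small)
gtoolsPerms <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- gtoolsPerms(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1, sub))
    out <- rbind(out, block)
  }
  out
}
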