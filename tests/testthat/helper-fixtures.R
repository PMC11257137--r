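# Shared in-code fixtures and the independent IPF oracle.

# Publication-style rounding (half away from zero), as printed tables use;
# base round() rounds half to even. Small epsilon absorbs binary
# representation error at the half boundary.
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-7) / m
}

toy_schema <- function() {
  survey_schema(list(
    color = c("Red", "Blue"),
    shape = c("Circle", "Square", "Triangle")))
}

toy_microdata <- function(n = 12, seed = 7) {
  set.seed(seed)
  sch <- toy_schema()
  df <- data.frame(
    color = sample(c("Red", "Blue"), n, replace = TRUE),
    shape = sample(c("Circle", "Square", "Triangle"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  validate_microdata(df, sch)
}

# Brute-force IPF on the 2-way contingency table: scale rows then columns
# of the cell-probability table until both margins match the targets.
# Deliberately independent of rake(): operates on the aggregated table and
# returns per-record weights via cell membership.
bruteforce_ipf_weights <- function(data, var1, var2, t1, t2,
                                   tol = 1e-13, max_iter = 100000L) {
  counts <- table(factor(data[[var1]], names(t1)),
                  factor(data[[var2]], names(t2)))
  m <- counts / sum(counts)
  for (i in seq_len(max_iter)) {
    m <- m * (t1 / rowSums(m))
    m <- t(t(m) * (t2 / colSums(m)))
    if (max(abs(rowSums(m) - t1)) < tol &&
        max(abs(colSums(m) - t2)) < tol) break
  }
  cell_w <- m / (counts / sum(counts))
  w <- cell_w[cbind(data[[var1]], data[[var2]])]
  w / mean(w)
}

random_two_var_problem <- function(seed) {
  set.seed(seed)
  r <- sample(2:5, 1)
  c <- sample(2:5, 1)
  lv1 <- paste0("a", seq_len(r))
  lv2 <- paste0("b", seq_len(c))
  # all cells occupied so the table IPF fixed point exists and is interior
  counts <- matrix(stats::rpois(r * c, 3) + 1L, r, c)
  n <- sum(counts)
  if (n > 200) {
    counts <- matrix(1L, r, c)
    n <- r * c
  }
  df <- data.frame(
    v1 = rep(rep(lv1, times = c), times = as.vector(counts)),
    v2 = rep(rep(lv2, each = r), times = as.vector(counts)),
    stringsAsFactors = FALSE)
  df <- df[sample(nrow(df)), , drop = FALSE]
  rownames(df) <- NULL
  t1 <- stats::setNames(prop.table(stats::runif(r, 0.2, 1)), lv1)
  t2 <- stats::setNames(prop.table(stats::runif(c, 0.2, 1)), lv2)
  sch <- survey_schema(list(v1 = lv1, v2 = lv2))
  list(microdata = validate_microdata(df, sch),
       targets = marginal_targets(list(v1 = t1, v2 = t2)))
}

# Small synthetic profile for unit tests (same stated world, reduced n).
small_synthetic_config <- function(seed = 11L) {
  default_synthetic_config(n_pop = 20000L, n_sample = 2000L, seed = seed)
}
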