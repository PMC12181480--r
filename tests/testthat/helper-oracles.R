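# Independent oracles used across the suite: brute-force implementations
# that stay deliberately naive (O(n^2) loops, direct definitions), plus a
# generator of small random survival datasets.

# product-limit by direct per-time recomputation
km_brute <- function(times, events) {
  ot <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ot))
  for (i in seq_along(ot)) {
    u <- ot[i]
    n <- sum(times >= u)
    d <- sum(times == u & events == 1)
    s <- s * (1 - d / n)
    out[i] <- s
  }
  list(time = ot, survival = out)
}

# log-rank chi-square by per-event-time 2x2 hypergeometric accumulation
logrank_brute <- function(ta, ea, tb, eb) {
  tt <- c(ta, tb)
  ee <- c(ea, eb)
  gg <- rep(c("a", "b"), c(length(ta), length(tb)))
  ot <- sort(unique(tt[ee == 1]))
  O <- E <- V <- 0
  for (u in ot) {
    atrisk <- tt >= u
    n <- sum(atrisk)
    n1 <- sum(atrisk & gg == "a")
    d <- sum(tt == u & ee == 1)
    d1 <- sum(tt == u & ee == 1 & gg == "a")
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Pearson correlation of average ranks, the definitional Spearman
spearman_brute <- function(x, y) {
  avg_rank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2)
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# small random survival dataset; tie = TRUE draws integer days (tied deaths)
rand_surv_data <- function(seed, tie = TRUE, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(40:120, 1)
  times <- if (tie) sample(5:40, n, replace = TRUE) else round(rexp(n, 1 / 30), 8)
  times <- pmax(times, 1e-3)
  ev <- stats::rbinom(n, 1, 0.85)
  if (sum(ev) == 0) ev[1] <- 1L
  d <- data.frame(
    age_days = times, event = ev,
    g = sample(letters[1:sample(2:3, 1)], n, replace = TRUE),
    s = sample(c("F", "M"), n, replace = TRUE))
  # guarantee both covariates vary
  d$g[1:2] <- c("a", "b")
  d$s[1:2] <- c("F", "M")
  d
}

# four canonical well-formed CSV rows as text
tiny_csv_text <- function() {
  paste(
    "lab,cohort,genotype,sex,diet,age_days,event",
    "Hoffman,1,CantonS,F,DR,45.5,1",
    "Hoffman,1,CantonS,F,AL,40,1",
    "Lyu,4,wDahomey,M,DR,61.25,0",
    "Lyu,4,w1118,M,AL,33,1",
    sep = "\n")
}

write_tiny_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(tiny_csv_text(), path)
  path
}
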