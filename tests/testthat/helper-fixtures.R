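# Random survival/expression fixtures, generated in code at test time.

random_surv <- function(n, event_frac = 0.7, allow_ties = FALSE) {
  tt <- rexp(n, rate = 0.1)
  if (allow_ties) tt <- ceiling(tt * 2) / 2      # coarse grid forces ties
  st <- rbinom(n, 1, event_frac)
  if (sum(st) == 0) st[sample.int(n, 1)] <- 1L
  survival_data(tt, st)
}

random_fixture <- function(n = 25, assoc = 0.5, allow_ties = FALSE) {
  x <- rnorm(n)
  tt <- rexp(n, rate = 0.1 * exp(assoc * x))
  if (allow_ties) tt <- ceiling(tt * 2) / 2
  st <- rbinom(n, 1, 0.75)
  if (sum(st) == 0) st[sample.int(n, 1)] <- 1L
  list(x = x, surv = survival_data(tt, st))
}

# Independent reference fit (oracle): survival::coxph with Breslow ties.
oracle_cox <- function(x, surv) {
  fit <- survival::coxph(survival::Surv(surv$time, surv$status) ~ x,
                         ties = "breslow")
  c(b = unname(stats::coef(fit)), se = sqrt(stats::vcov(fit)[1, 1]))
}
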