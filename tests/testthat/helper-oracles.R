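# Independent oracles used to freeze or cross-check expected values.

# Classical balanced two-way ANOVA decomposition from cell means (brute
# force): valid oracle for balanced designs, where Type II equals Type I.
brute_force_anova <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  grand <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  nA <- table(A); nB <- table(B); nAB <- table(A, B)
  ss_a <- sum(nA * (mA - grand)^2)
  ss_b <- sum(nB * (mB - grand)^2)
  ss_int <- sum(nAB * (sweep(sweep(mAB, 1, mA), 2, mB) + grand)^2)
  ss_res <- sum((y - mAB[cbind(A, B)])^2)
  list(ss = c(group = ss_a, bin = ss_b, int = ss_int, res = ss_res),
       df = c(nlevels(A) - 1, nlevels(B) - 1,
              (nlevels(A) - 1) * (nlevels(B) - 1),
              length(y) - nlevels(A) * nlevels(B)))
}

# Expected g-ratio of one simulated subgroup, accounting for the truncated
# normal and the joint (a, g) rejection against the fiber cap:
# E[g | accept] with acceptance probability P(a <= cap * g | g) under the
# log-normal axon model.  Computed by numerical integration, independent of
# the sampler.
implied_subgroup_mean_g <- function(mu_g, config) {
  lb <- config$g_bounds[1]; ub <- config$g_bounds[2]
  dens <- function(g) stats::dnorm(g, mu_g, config$g_sd) *
    stats::plnorm(config$fiber_cap * g, config$axon_log_mu,
                  config$axon_log_sigma)
  num <- stats::integrate(function(g) g * dens(g), lb, ub, rel.tol = 1e-10)$value
  den <- stats::integrate(dens, lb, ub, rel.tol = 1e-10)$value
  num / den
}
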