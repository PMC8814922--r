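# Trial power calculators: two-arm power for the mean of repeated
# follow-up HDRS-17 scores with baseline (ANCOVA) adjustment and dropout,
# and Fisher-z correlation power / minimum detectable correlation.

#' Construct a trial design
#'
#' Parameters of the repeated-follow-up comparison: a between-arm
#' difference `effect` in the mean of `k_followups` follow-up scores with
#' common standard deviation `sd`, compound-symmetric correlation
#' `r_follow` between follow-ups, a baseline covariate correlating
#' `r_baseline` with each follow-up, and uniform `dropout` before analysis.
#'
#' @param n_total total randomized sample size (both arms).
#' @param effect between-arm difference in score points (default 3, the
#'   minimum clinically important HDRS-17 difference).
#' @param sd score standard deviation in points (default 8).
#' @param r_follow correlation between follow-up measurements (default 0.7).
#' @param r_baseline baseline-to-follow-up correlation (default 0.27).
#' @param k_followups number of follow-up measurements (default 3).
#' @param dropout fraction lost to follow-up (default 0.2).
#' @param alpha significance level (default 0.05).
#' @param tails 1 or 2 (default 2).
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_total, effect = 3, sd = 8, r_follow = 0.7,
                         r_baseline = 0.27, k_followups = 3, dropout = 0.2,
                         alpha = 0.05, tails = 2) {
  stopifnot(n_total >= 4, sd > 0, k_followups >= 1,
            r_follow >= 0, r_follow < 1, r_baseline >= 0, r_baseline < 1,
            dropout >= 0, dropout < 1, alpha > 0, alpha < 1,
            tails %in% c(1, 2))
  structure(list(n_total = n_total, effect = effect, sd = sd,
                 r_follow = r_follow, r_baseline = r_baseline,
                 k_followups = k_followups, dropout = dropout,
                 alpha = alpha, tails = tails),
            class = "trial_design")
}

#' Power for a difference in the mean of repeated follow-ups
#'
#' Normal-approximation power for a two-arm comparison of the mean of k
#' correlated follow-up scores, adjusted for a baseline covariate and for
#' dropout:
#' \deqn{\mathrm{var}(\bar Y) = \sigma^2 \frac{1 + (k-1) r_f}{k}}
#' reduced by the squared correlation between baseline and the follow-up
#' mean, \eqn{r_{bm} = r_b \sqrt{k / (1 + (k-1) r_f)}} (the ANCOVA variance
#' reduction); the per-arm analysed n is `round(n_total * (1 - dropout) / 2)`
#' — a whole number of participants per arm; and
#' \deqn{\mathrm{power} = \Phi(\delta / se - z_{1-\alpha/\mathrm{tails}}),
#'   \quad se = \sigma_{adj}\sqrt{2 / n_{arm}}.}
#'
#' A Student-t variant (noncentral t with 2 n_arm - 2 df) is available via
#' `use_t = TRUE`.
#'
#' @param design a `trial_design`.
#' @param use_t use the noncentral-t computation instead of the normal
#'   approximation (default FALSE).
#' @return Power as a fraction in (0, 1).
#' @export
power_mean_followups <- function(design, use_t = FALSE) {
  stopifnot(inherits(design, "trial_design"))
  d <- design
  v_mean <- d$sd^2 * (1 + (d$k_followups - 1) * d$r_follow) / d$k_followups
  r_bm <- d$r_baseline * sqrt(d$k_followups /
                                (1 + (d$k_followups - 1) * d$r_follow))
  v_adj <- v_mean * (1 - r_bm^2)
  n_arm <- round(d$n_total * (1 - d$dropout) / 2)
  if (n_arm < 2) stop("fewer than 2 analysable participants per arm")
  se <- sqrt(v_adj) * sqrt(2 / n_arm)
  ncp <- d$effect / se
  if (use_t) {
    df <- 2 * n_arm - 2
    1 - stats::pt(stats::qt(1 - d$alpha / d$tails, df), df, ncp = ncp)
  } else {
    pnorm(ncp - qnorm(1 - d$alpha / d$tails))
  }
}

#' Power to detect a correlation via the Fisher z transform
#'
#' \deqn{\mathrm{power} = \Phi(|z(\rho_1) - z(\rho_0)| \sqrt{n-3}
#'   - z_{1-\alpha/\mathrm{tails}})}
#' with \eqn{z(\rho) = \mathrm{atanh}(\rho)}.
#'
#' @param n sample size (> 3).
#' @param rho0 null-hypothesis correlation.
#' @param rho1 alternative-hypothesis correlation.
#' @param alpha significance level (default 0.05).
#' @param tails 1 or 2 (default 2).
#' @return Power as a fraction.
#' @export
power_correlation <- function(n, rho0, rho1, alpha = 0.05, tails = 2) {
  stopifnot(n > 3, abs(rho0) < 1, abs(rho1) < 1, alpha > 0, alpha < 1,
            tails %in% c(1, 2))
  pnorm(abs(atanh(rho1) - atanh(rho0)) * sqrt(n - 3) -
          qnorm(1 - alpha / tails))
}

#' Minimum detectable correlation magnitude
#'
#' Inverts the Fisher-z power formula:
#' \deqn{|\rho| = \tanh\!\big(z(\rho_0) + (z_{1-\alpha/\mathrm{tails}}
#'   + z_{\mathrm{power}}) / \sqrt{n-3}\big)}
#' No rounding is applied; round only at presentation.
#'
#' @param n sample size (> 3).
#' @param power target power in (alpha, 1).
#' @param alpha significance level (default 0.05).
#' @param tails 1 or 2 (default 1).
#' @param rho0 null correlation (default 0).
#' @return Required correlation magnitude.
#' @export
required_correlation <- function(n, power, alpha = 0.05, tails = 1,
                                 rho0 = 0) {
  stopifnot(n > 3, power > alpha, power < 1, tails %in% c(1, 2))
  tanh(atanh(rho0) + (qnorm(1 - alpha / tails) + qnorm(power)) / sqrt(n - 3))
}
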