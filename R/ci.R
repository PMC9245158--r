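#' Variance of an estimate under the Greenwood or bootstrap option
#'
#' Under the `greenwood` option, population-kind quantities are treated as
#' fixed (variance zero) and excess-kind cumulative hazards take the Greenwood
#' variance of their observed counterpart; other quantities use their own
#' Greenwood series. Under the `bootstrap` option the sample variance of the
#' replicates (denominator `B - 1`) is returned.
#'
#' @param estimate The point estimate (used only for its length).
#' @param option `"greenwood"` or `"bootstrap"`.
#' @param greenwood Greenwood variance value(s) of the observed counterpart
#'   (required for `option = "greenwood"` unless `kind = "population"`).
#' @param replicates Numeric vector of bootstrap replicate values (required
#'   for `option = "bootstrap"`); `NA` replicates are dropped.
#' @param kind `"observed"`, `"population"` or `"excess"`.
#' @return Variance, same length as `estimate`.
#' @export
variance_of <- function(estimate, option = c("greenwood", "bootstrap"),
                        greenwood = NULL, replicates = NULL,
                        kind = "observed") {
  option <- match.arg(option)
  if (option == "greenwood") {
    if (kind == "population") return(rep(0, length(estimate)))
    if (is.null(greenwood)) stop("greenwood variance series not supplied")
    return(greenwood)
  }
  if (is.null(replicates)) stop("bootstrap variance requested without replicates")
  var(replicates[!is.na(replicates)])
}

#' Confidence intervals for hazards and transition probabilities
#'
#' Six constructions: symmetric plain-scale intervals with Greenwood
#' (`plain.G`) or bootstrap (`plain.boot`) variance; the delta-method
#' log-scale interval (`log.boot`); empirical bootstrap quantiles (`q.boot`,
#' type-7 interpolation); and logit- and complementary-log-log-scale intervals
#' (`logit.boot`, `cloglog.boot`). Plain intervals are not clipped to `[0, 1]`
#' and may fall outside it.
#'
#' @param theta_hat Point estimate.
#' @param variance Variance estimate (ignored by `q.boot`). For `plain.G`
#'   supply the Greenwood variance; for the `.boot` methods the bootstrap
#'   variance.
#' @param replicates Bootstrap replicate values (used by `q.boot` only).
#' @param method One of `"plain.G"`, `"plain.boot"`, `"log.boot"`,
#'   `"q.boot"`, `"logit.boot"`, `"cloglog.boot"`.
#' @param alpha Significance level (default 0.05 for 95% intervals).
#' @return A tibble `method`, `estimate`, `lower`, `upper`, `alpha`.
#' @examples
#' confidence_interval(0.5, variance = 0.01, method = "plain.G")
#' confidence_interval(0.5, variance = 0.01, method = "log.boot")
#' @export
confidence_interval <- function(theta_hat, variance = NULL, replicates = NULL,
                                method = c("plain.G", "plain.boot", "log.boot",
                                           "q.boot", "logit.boot", "cloglog.boot"),
                                alpha = 0.05) {
  method <- match.arg(method)
  z <- qnorm(1 - alpha / 2)
  if (method == "q.boot") {
    if (is.null(replicates)) stop("q.boot requires bootstrap replicates")
    r <- replicates[!is.na(replicates)]
    q <- unname(quantile(r, c(alpha / 2, 1 - alpha / 2), type = 7))
    lower <- q[1]; upper <- q[2]
  } else {
    if (is.null(variance)) stop(method, " requires a variance estimate")
    se <- sqrt(variance)
    if (method %in% c("plain.G", "plain.boot")) {
      lower <- theta_hat - z * se
      upper <- theta_hat + z * se
    } else if (method == "log.boot") {
      if (theta_hat <= 0) stop("log.boot requires theta_hat > 0")
      lower <- theta_hat * exp(-z * se / theta_hat)
      upper <- theta_hat * exp(z * se / theta_hat)
    } else if (method == "logit.boot") {
      if (theta_hat <= 0 || theta_hat >= 1) {
        stop("logit.boot requires 0 < theta_hat < 1")
      }
      lg <- log(theta_hat / (1 - theta_hat))
      shift <- z * se / (theta_hat * (1 - theta_hat))
      bounds <- sort(stats::plogis(c(lg - shift, lg + shift)))
      lower <- bounds[1]; upper <- bounds[2]
    } else { # cloglog.boot
      if (theta_hat <= 0 || theta_hat >= 1) {
        stop("cloglog.boot requires 0 < theta_hat < 1")
      }
      base <- log(-log(theta_hat))
      shift <- z * se / (theta_hat * log(theta_hat))
      bounds <- sort(exp(-exp(c(base - shift, base + shift))))
      lower <- bounds[1]; upper <- bounds[2]
    }
  }
  tibble::tibble(method = method, estimate = theta_hat,
                 lower = lower, upper = upper, alpha = alpha)
}
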