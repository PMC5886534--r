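#' Polynomial regression link between study and auxiliary variables
#'
#' Constructs the link model `y = lambda(x1, ..., xp) + eps` with
#' `lambda` a polynomial of degree at most 2 in each auxiliary variable and
#' `eps` a homoscedastic normal error. The per-stratum variance of `lambda`
#' enters the stratification objective through the squared coefficients and
#' the conditional truncated moments of each auxiliary distribution.
#'
#' @param intercept intercept `beta0` (does not affect stratum variances).
#' @param terms a data frame with columns `variable` (integer index of the
#'   auxiliary variable), `power` (1 or 2) and `coefficient`, or a named
#'   numeric vector with names like `"x1"`, `"x2^2"`.
#' @param error_scale positive standard deviation of the error term; defaults
#'   to 1, matching the standard-normal error used in the parametric
#'   objective.
#' @return an object of class `"link_model"`.
#' @examples
#' link_model(terms = c(x1 = 3, x2 = -1))
#' link_model(terms = c(x1 = 1, `x1^2` = 0.5))
#' @export
link_model <- function(intercept = 0, terms, error_scale = 1) {
  if (!is.data.frame(terms)) {
    terms <- .parse_terms(terms)
  }
  stopifnot(all(c("variable", "power", "coefficient") %in% names(terms)))
  if (nrow(terms) < 1) stop("at least one term is required")
  if (!all(terms$power %in% c(1, 2))) stop("powers must be 1 or 2")
  if (anyDuplicated(terms[c("variable", "power")])) {
    stop("each (variable, power) pair may appear only once")
  }
  if (!is.finite(error_scale) || error_scale <= 0) {
    stop("'error_scale' must be positive")
  }
  structure(list(intercept = intercept,
                 terms = terms[order(terms$variable, terms$power), ,
                               drop = FALSE],
                 error_scale = error_scale,
                 metrics = NULL),
            class = "link_model")
}

# "x1" -> (1, 1); "x3^2" -> (3, 2). Accepts a named numeric vector.
.parse_terms <- function(v) {
  stopifnot(is.numeric(v), !is.null(names(v)))
  m <- regmatches(names(v), regexec("^x([0-9]+)(\\^([12]))?$", names(v)))
  bad <- vapply(m, length, 1L) == 0
  if (any(bad)) {
    stop("cannot parse term(s): ", paste(names(v)[bad], collapse = ", "),
         " (expected \"x<i>\" or \"x<i>^2\")")
  }
  data.frame(
    variable = vapply(m, function(g) as.integer(g[2]), 1L),
    power = vapply(m, function(g) if (g[4] == "") 1L else as.integer(g[4]), 1L),
    coefficient = unname(v))
}

#' Fit the link model to a population table
#'
#' Least-squares fit of the polynomial link on a population table with
#' columns `x1..xp` (auxiliary variables) and the response. Alongside the
#' coefficients the model-comparison metrics are computed: the multiple
#' correlation `sqrt(R^2)`, the residual standard error
#' `RSE = sqrt(SSE / (n - p - 1))`, the adjusted R-squared, and AIC under
#' the Gaussian-likelihood convention of [stats::AIC()].
#'
#' @param data a data frame containing the term variables and the response.
#' @param response name of the response column (default `"y"`).
#' @param terms character vector of term labels such as `c("x1", "x2")` or
#'   `c("x1", "x1^2")`.
#' @param error_mode `"rse"` sets the model's `error_scale` to the fitted
#'   RSE; `"unit"` keeps the standard-normal error scale of 1 used by the
#'   parametric objective construction.
#' @return a `"link_model"` with fitted coefficients and a `metrics` list
#'   (`correlation`, `rse`, `adj_r_squared`, `aic`, `n`), plus the underlying
#'   `lm` fit in attribute `"lm"`.
#' @export
fit_link <- function(data, response = "y", terms, error_mode = c("unit", "rse")) {
  error_mode <- match.arg(error_mode)
  stopifnot(is.data.frame(data))
  if (!response %in% names(data)) stop("response column '", response, "' not found")
  tdf <- .parse_terms(stats::setNames(rep(NA_real_, length(terms)), terms))
  vars <- paste0("x", tdf$variable)
  missing_vars <- setdiff(unique(vars), names(data))
  if (length(missing_vars)) {
    stop("variable column(s) not found: ", paste(missing_vars, collapse = ", "))
  }
  n <- nrow(data)
  p <- nrow(tdf)
  if (n <= p + 1) stop("need more observations than parameters + 1")

  X <- mapply(function(v, k) data[[paste0("x", v)]]^k,
              tdf$variable, tdf$power)
  X <- matrix(X, nrow = n)
  colnames(X) <- terms
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    dropped <- terms[qrX$pivot[seq.int(qrX$rank + 1, ncol(X) + 1)] - 1]
    stop("collinear design: term(s) ", paste(dropped, collapse = ", "),
         " are linearly dependent on the others")
  }
  df <- data.frame(.y = data[[response]], X, check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", terms),
                                               collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  sse <- sum(stats::residuals(fit)^2)
  rse <- sqrt(sse / (n - p - 1))
  r2 <- summary(fit)$r.squared
  metrics <- list(correlation = sqrt(max(r2, 0)),
                  rse = rse,
                  adj_r_squared = summary(fit)$adj.r.squared,
                  aic = stats::AIC(fit),
                  n = n)
  tdf$coefficient <- unname(stats::coef(fit)[-1])
  out <- link_model(intercept = unname(stats::coef(fit)[1]),
                    terms = tdf,
                    error_scale = if (error_mode == "rse") rse else 1)
  out$metrics <- metrics
  attr(out, "lm") <- fit
  out
}

#' @export
print.link_model <- function(x, ...) {
  lbl <- with(x$terms, paste0("x", variable, ifelse(power == 2, "^2", "")))
  eq <- paste0(format(x$intercept, digits = 4), " + ",
               paste(sprintf("%s*%s", format(x$terms$coefficient, digits = 4),
                             lbl), collapse = " + "))
  cat("<link_model> lambda(x) =", eq, "\n")
  cat("  error scale:", format(x$error_scale, digits = 4), "\n")
  if (!is.null(x$metrics)) {
    cat(sprintf("  fit: correlation %.4f | RSE %.4f | Adj R^2 %.4f | AIC %.2f\n",
                x$metrics$correlation, x$metrics$rse,
                x$metrics$adj_r_squared, x$metrics$aic))
  }
  invisible(x)
}

#' Per-stratum variance of the link function
#'
#' Variance of `lambda(x1, ..., xp)` conditional on a stratum, from the
#' conditional raw moments of each auxiliary variable. Variables are treated
#' as independent within strata, so each variable's polynomial contributes
#' its own conditional variance and cross-variable covariances are zero:
#' a linear term contributes `beta^2 * sigma_hx^2`, and a linear + quadratic
#' pair in the same variable contributes
#' `Var(b1*X + b2*X^2) = sum_{i,j} b_i b_j (m_{i+j} - m_i m_j)`.
#'
#' @param model a [link_model].
#' @param moments a named list, one element per variable appearing in the
#'   model (names `"x1"`, `"x2"`, ...), each a numeric vector of conditional
#'   raw moments `c(m1, m2, ...)` up to the order the model requires (2 for a
#'   linear term, 4 when a quadratic term is present).
#' @return nonnegative variance of the link over the stratum.
#' @examples
#' m <- link_model(terms = c(x1 = 2, x2 = 3))
#' # variances 0.04 and 0.01 with unit means
#' lambda_stratum_variance(m, list(x1 = c(1, 1.04), x2 = c(1, 1.01)))
#' @export
lambda_stratum_variance <- function(model, moments) {
  stopifnot(inherits(model, "link_model"))
  total <- 0
  for (v in unique(model$terms$variable)) {
    tv <- model$terms[model$terms$variable == v, , drop = FALSE]
    key <- paste0("x", v)
    if (is.null(moments[[key]])) stop("moments for variable ", key, " are missing")
    m <- moments[[key]]
    need <- 2 * max(tv$power)
    if (length(m) < need) {
      stop("variable ", key, " requires conditional moments up to order ", need)
    }
    mom <- function(k) if (k == 0) 1 else m[k]
    contrib <- 0
    for (i in seq_len(nrow(tv))) {
      for (j in seq_len(nrow(tv))) {
        contrib <- contrib + tv$coefficient[i] * tv$coefficient[j] *
          (mom(tv$power[i] + tv$power[j]) - mom(tv$power[i]) * mom(tv$power[j]))
      }
    }
    total <- total + contrib
  }
  max(total, 0)
}
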