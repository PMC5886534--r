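#' Run the full stratification workflow from a configuration
#'
#' Config-driven orchestration intended for scripted or command-line use.
#' The configuration (an R list, or a path to a JSON/YAML file) names
#' exactly one input source and the design parameters; the workflow scales
#' the variables, fits distributions and the link, solves the boundary
#' problem for every requested strata count, allocates samples, and writes
#' machine- and human-readable reports. All computation is full precision;
#' boundaries are rounded (2 decimals) only in the human-readable CSV.
#'
#' Config fields:
#' \describe{
#'   \item{input}{exactly one of `csv` (path to a population table with a
#'     header row), `population` (inline synthetic-population spec:
#'     `N`, `aux` = list of `list(family, shape, scale, location)`, `link` =
#'     named coefficient list, `noise_sd`, `seed`), or `problem` (fully
#'     parametric: `components` = list of `list(family, shape, scale,
#'     location, beta)`, `y0`, `d`, optional `error_scale`).}
#'   \item{response, terms}{model columns for table input (e.g.
#'     `terms = c("x1", "x2")`; quadratics as `"x1^2"`).}
#'   \item{family}{`"auto"`, or per-variable families.}
#'   \item{L}{a strata count or vector of counts.}
#'   \item{n, N}{total sample size and population size.}
#'   \item{npts, refine, error_mode, y0, d}{optimizer settings, all
#'     optional.}
#' }
#'
#' @param config list or path to a JSON/YAML configuration file.
#' @param outdir optional directory for `result.json`, `result.csv` and
#'   (for an L range) `profile.csv`; created if missing. `NULL` writes
#'   nothing.
#' @return the report list (invisibly when `outdir` is given): per-L blocks
#'   with boundaries, sample sizes and objective, plus fit metadata.
#' @export
run_stratification <- function(config, outdir = NULL) {
  if (is.character(config)) config <- .read_config(config)
  stopifnot(is.list(config))
  sources <- intersect(names(config), c("csv", "population", "problem"))
  if (length(sources) != 1) {
    stop("config must name exactly one input source: csv, population or problem")
  }
  L <- as.integer(config$L %||% 2L)
  n <- config$n %||% 100L
  npts <- config$npts %||% 1000L
  refine <- config$refine %||% 10L
  error_mode <- config$error_mode %||% "unit"

  if (sources == "problem") {
    report <- .run_parametric(config, L, n, npts, refine)
  } else {
    tab <- if (sources == "csv") {
      utils::read.csv(config$csv)
    } else {
      generate_population(.population_from_config(config$population))
    }
    terms <- unlist(config$terms %||% grep("^x[0-9]+$", names(tab), value = TRUE))
    response <- config$response %||% "y"
    fml_terms <- sub("^(x[0-9]+)\\^2$", "I(\\1^2)", terms)
    fml <- stats::as.formula(paste(
      if (response %in% names(tab)) response else "",
      "~", paste(fml_terms, collapse = "+")))
    fit <- optStrata(fml, tab, L = L, n = n,
                     N = config$N %||% nrow(tab),
                     family = unlist(config$family %||% "auto"),
                     coefs = .coefs_from_config(config$coefs),
                     error_mode = error_mode,
                     y0 = config$y0, d = config$d,
                     npts = npts, refine = refine)
    report <- .report_from_fit(fit)
  }
  if (!is.null(outdir)) {
    .write_report(report, outdir)
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_config <- function(path) {
  if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    # keep record lists as lists; only scalars/vectors are simplified
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
}

.dist_from_config <- function(x) {
  dist_spec(x$family, shape = x$shape, scale = x$scale, location = x$location)
}

.coefs_from_config <- function(x) {
  if (is.null(x)) return(NULL)
  stats::setNames(as.numeric(unlist(x)), names(x))
}

.population_from_config <- function(pc) {
  aux <- lapply(pc$aux, .dist_from_config)
  population_spec(N = pc$N, aux = aux,
                  link = link_model(intercept = pc$intercept %||% 0,
                                    terms = .coefs_from_config(pc$link)),
                  noise_sd = pc$noise_sd %||% 1,
                  seed = pc$seed %||% 1L)
}

.run_parametric <- function(config, L, n, npts, refine) {
  pc <- config$problem
  components <- lapply(pc$components, function(cm) {
    list(dist = .dist_from_config(cm), beta = as.numeric(cm$beta %||% 1))
  })
  designs <- list()
  for (Lk in sort(unique(L))) {
    pr <- strat_problem(components, y0 = pc$y0, d = pc$d, L = Lk,
                        error_scale = pc$error_scale, npts = npts)
    dsn <- dp_solve(pr)
    if (refine > 1) dsn <- refine_design(pr, dsn, factor = refine)
    if (!is.null(config$N)) dsn <- allocate(dsn, n = n, N = config$N)
    designs[[as.character(Lk)]] <- dsn
  }
  list(kind = "parametric",
       domain = list(y0 = pc$y0, d = pc$d), rescale = 1,
       designs = lapply(designs, .design_block, rescale = 1),
       profile = if (length(L) > 1) {
         data.frame(L = sort(unique(L)),
                    objective = vapply(designs, `[[`, 0, "total"),
                    variance = vapply(designs, `[[`, 0, "total")^2 / n)
       })
}

.design_block <- function(dsn, rescale) {
  list(L = dsn$L,
       boundaries = as.numeric(dsn$boundaries * rescale),
       boundaries_scaled = as.numeric(dsn$boundaries),
       widths = as.numeric(dsn$widths),
       phi = as.numeric(dsn$phi),
       objective = dsn$total,
       n_h = if (!is.null(dsn$allocation)) as.integer(dsn$allocation$n_h),
       N_h = if (!is.null(dsn$allocation)) as.integer(dsn$allocation$N_h))
}

.report_from_fit <- function(fit) {
  list(kind = "fitted",
       domain = list(y0 = fit$y0, d = fit$d), rescale = fit$rescale,
       scale_factors = as.list(fit$scale_factors),
       distributions = lapply(fit$dist_fits, function(f) {
         list(family = f$dist$family, shape = f$dist$shape,
              scale = f$dist$scale, location = f$dist$location,
              logLik = f$logLik, ks_statistic = f$ks_statistic,
              ks_p_value = f$ks_p_value)
       }),
       regression = if (!is.null(fit$link$metrics)) {
         c(list(intercept = fit$link$intercept,
                coefficients = stats::setNames(
                  as.list(fit$link$terms$coefficient),
                  paste0("x", fit$link$terms$variable,
                         ifelse(fit$link$terms$power == 2, "^2", "")))),
           fit$link$metrics)
       },
       designs = lapply(fit$designs, .design_block, rescale = fit$rescale),
       profile = if (!is.null(fit$profile)) {
         as.data.frame(fit$profile)[c("L", "objective", "variance")]
       })
}

.write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(outdir, "result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  rows <- lapply(report$designs, function(b) {
    data.frame(L = b$L,
               OSB = paste(sprintf("%.2f", b$boundaries), collapse = " | "),
               n_h = if (is.null(b$n_h)) "" else paste(b$n_h, collapse = " | "),
               objective = b$objective)
  })
  utils::write.csv(do.call(rbind, rows), file.path(outdir, "result.csv"),
                   row.names = FALSE)
  if (!is.null(report$profile)) {
    utils::write.csv(report$profile, file.path(outdir, "profile.csv"),
                     row.names = FALSE)
  }
  invisible(NULL)
}
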