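#' Uncertain model quantity
#'
#' The atom of the model's input table: a point estimate together with an
#' uncertainty range and the distribution family used for probabilistic
#' sensitivity analysis. Probabilities carry beta distributions, costs gamma,
#' relative risks lognormal; `fixed` denotes a quantity that is never sampled.
#'
#' When no range is supplied, a +/-10% range around the point estimate is
#' generated (the convention used for inputs whose sources report no
#' variance), and the quantity is marked as having an auto-derived range so
#' that the range follows the value if the value is later overridden.
#'
#' @param value Non-negative point estimate (probability as a fraction in
#'   \[0,1\], cost in 2021 R$, or a unitless relative risk).
#' @param low,high Lower/upper bound of the uncertainty range, read downstream
#'   as a 95% interval. Both `NULL` to auto-derive a +/-10% range.
#' @param family Distribution family, one of `"beta"`, `"gamma"`,
#'   `"lognormal"`, `"fixed"`.
#' @return An object of class `uncertain_quantity`: a list with fields
#'   `value`, `low`, `high`, `family`, `auto_range`.
#' @export
uncertain_quantity <- function(value, low = NULL, high = NULL,
                               family = c("beta", "gamma", "lognormal", "fixed")) {
  family <- match.arg(family)
  auto <- is.null(low) && is.null(high)
  if (auto) {
    low <- 0.9 * value
    high <- 1.1 * value
  }
  if (is.null(low) || is.null(high))
    stop("supply both 'low' and 'high', or neither")
  structure(list(value = as.numeric(value), low = as.numeric(low),
                 high = as.numeric(high), family = family, auto_range = auto),
            class = "uncertain_quantity")
}

# Registry of the model's uncertain quantities: canonical key, measurement
# kind, distribution family, default point value, and default range (NA range
# means "no source variance" -> auto +/-10%). Single source of truth for
# defaults, validation, serialization, and PSA sampling order.
.vte_registry <- function() {
  reg <- rbind(
    data.frame(key = "p_dvt_baseline",      kind = "prob", family = "beta",      value = 0.007,  low = 0.001, high = 0.03),
    data.frame(key = "p_pe_given_dvt",      kind = "prob", family = "beta",      value = 0.20,   low = 0.15,  high = 0.25),
    data.frame(key = "p_minor_baseline",    kind = "prob", family = "beta",      value = 0.068,  low = 0.03,  high = 0.10),
    data.frame(key = "p_major_baseline",    kind = "prob", family = "beta",      value = 0.014,  low = 0.006, high = 0.02),
    data.frame(key = "p_mortality",         kind = "prob", family = "beta",      value = 0.0026, low = NA,    high = NA),
    data.frame(key = "p_hypo_baseline",     kind = "prob", family = "beta",      value = 0.6629, low = NA,    high = NA),
    data.frame(key = "c_dvt",               kind = "cost", family = "gamma",     value = 9524,   low = 7486,  high = 12036),
    data.frame(key = "c_pe",                kind = "cost", family = "gamma",     value = 10618,  low = 7666,  high = 13557),
    data.frame(key = "c_minor",             kind = "cost", family = "gamma",     value = 4479,   low = NA,    high = NA),
    data.frame(key = "c_major",             kind = "cost", family = "gamma",     value = 36730,  low = NA,    high = NA),
    data.frame(key = "c_hypo",              kind = "cost", family = "gamma",     value = 30,     low = 20,    high = 40),
    data.frame(key = "c_lmwh",              kind = "cost", family = "gamma",     value = 50,     low = NA,    high = NA),
    data.frame(key = "c_ipc",               kind = "cost", family = "gamma",     value = 102,    low = NA,    high = NA),
    data.frame(key = "rr_ipc_vs_lmwh_vte",  kind = "rr",   family = "lognormal", value = 0.87,   low = 0.08,  high = 9.50),
    data.frame(key = "rr_lmwh_dvt",         kind = "rr",   family = "lognormal", value = 0.33,   low = 0.01,  high = 7.93),
    data.frame(key = "rr_lmwh_minor",       kind = "rr",   family = "lognormal", value = 2.12,   low = 1.15,  high = 3.93),
    data.frame(key = "rr_lmwh_major",       kind = "rr",   family = "lognormal", value = 1.48,   low = 0.25,  high = 8.72),
    data.frame(key = "rr_compression_hypo", kind = "rr",   family = "lognormal", value = 0.36,   low = 0.22,  high = 0.56)
  )
  reg
}

#' Default model parameter set
#'
#' Builds the in-code default parameter set for the cesarean-delivery
#' thromboprophylaxis model: baseline adverse-event incidences under no
#' prophylaxis (as fractions), per-event management costs and prophylaxis
#' costs in 2021 Brazilian Real, the relative risks linking the prophylaxis
#' strategies to the baselines, the willingness-to-pay threshold (R$15,000
#' per adverse event avoided), and probabilistic-analysis settings (1,000
#' Monte Carlo draws). Quantities whose sources report no variance receive an
#' auto-derived +/-10% range.
#'
#' @return An object of class `vte_params`: list with `quantities` (named
#'   list of [uncertain_quantity()]), `wtp`, `n_psa`, `rng_seed`.
#' @examples
#' p <- default_parameters()
#' p$quantities$p_hypo_baseline$value  # 0.6629
#' @export
default_parameters <- function() {
  reg <- .vte_registry()
  q <- vector("list", nrow(reg))
  names(q) <- reg$key
  for (i in seq_len(nrow(reg))) {
    if (is.na(reg$low[i])) {
      q[[i]] <- uncertain_quantity(reg$value[i], family = reg$family[i])
    } else {
      q[[i]] <- uncertain_quantity(reg$value[i], reg$low[i], reg$high[i],
                                   family = reg$family[i])
    }
  }
  params <- structure(list(quantities = q, wtp = 15000, n_psa = 1000L,
                           rng_seed = 1L),
                      class = "vte_params")
  validate_parameters(params)
  params
}

# Shorthand accessor for a quantity's point value.
.pv <- function(params, key) params$quantities[[key]]$value

# Replace a quantity's point value, keeping the invariant low <= value <= high:
# auto-derived ranges are regenerated, source ranges are widened if needed.
# Internal workhorse for sensitivity analyses and PSA draws.
.set_value <- function(params, key, value) {
  q <- params$quantities[[key]]
  if (is.null(q)) stop("unknown parameter key: ", key)
  q$value <- value
  if (isTRUE(q$auto_range)) {
    q$low <- 0.9 * value
    q$high <- 1.1 * value
  } else {
    q$low <- min(q$low, value)
    q$high <- max(q$high, value)
  }
  params$quantities[[key]] <- q
  params
}

#' Validate a parameter set
#'
#' Checks every invariant of the model inputs: probabilities (and their
#' ranges) in \[0,1\], costs non-negative, relative risks strictly positive,
#' ranges ordered `low <= value <= high`, distribution families matching the
#' measurement kind (beta for probabilities, gamma for costs, lognormal for
#' relative risks), positive willingness-to-pay and iteration count. All
#' violations are collected and reported together, each naming the offending
#' key.
#'
#' @param params A `vte_params` object.
#' @return `params`, invisibly, if valid; otherwise an error listing every
#'   violated invariant.
#' @export
validate_parameters <- function(params) {
  if (!inherits(params, "vte_params"))
    stop("'params' must be a 'vte_params' object")
  reg <- .vte_registry()
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  for (i in seq_len(nrow(reg))) {
    key <- reg$key[i]
    q <- params$quantities[[key]]
    if (is.null(q)) {
      add(sprintf("%s: missing quantity", key))
      next
    }
    vals <- c(q$value, q$low, q$high)
    if (!all(is.finite(vals))) {
      add(sprintf("%s: non-finite value/low/high", key))
      next
    }
    if (q$low > q$value || q$value > q$high)
      add(sprintf("%s: range must satisfy low <= value <= high (got %g, %g, %g)",
                  key, q$low, q$value, q$high))
    kind <- reg$kind[i]
    if (kind == "prob") {
      if (q$value < 0 || q$value > 1 || q$low < 0 || q$high > 1)
        add(sprintf("%s: probability and its range must lie in [0,1]", key))
      if (!q$family %in% c("beta", "fixed"))
        add(sprintf("%s: probabilities take a beta (or fixed) distribution", key))
    } else if (kind == "cost") {
      if (q$value < 0 || q$low < 0)
        add(sprintf("%s: costs must be non-negative", key))
      if (!q$family %in% c("gamma", "fixed"))
        add(sprintf("%s: costs take a gamma (or fixed) distribution", key))
    } else if (kind == "rr") {
      if (q$value <= 0 || q$low <= 0)
        add(sprintf("%s: relative risks must be strictly positive", key))
      if (!q$family %in% c("lognormal", "fixed"))
        add(sprintf("%s: relative risks take a lognormal (or fixed) distribution", key))
    }
  }
  if (!is.numeric(params$wtp) || length(params$wtp) != 1 ||
      !is.finite(params$wtp) || params$wtp <= 0)
    add("wtp: willingness-to-pay must be a positive number")
  if (!is.numeric(params$n_psa) || length(params$n_psa) != 1 ||
      !is.finite(params$n_psa) || params$n_psa < 1 ||
      params$n_psa != round(params$n_psa))
    add("n_psa: iteration count must be a positive integer")
  if (!is.numeric(params$rng_seed) || length(params$rng_seed) != 1 ||
      !is.finite(params$rng_seed) || params$rng_seed != round(params$rng_seed))
    add("rng_seed: seed must be an integer")
  if (length(problems))
    stop("invalid parameter set:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  invisible(params)
}

# Format a double so that it survives a text round trip bit-exactly:
# 15 significant digits when that already round-trips, else 17.
.fmt_num <- function(x) {
  s <- formatC(x, digits = 15, format = "g", width = -1)
  if (as.numeric(s) != x) s <- sprintf("%.17g", x)
  s
}

.parse_config_lines <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regexpr("=", ln, fixed = TRUE)
    if (m < 0) stop("configuration line is not 'key = value': ", sQuote(ln))
    key <- trimws(substr(ln, 1, m - 1))
    val <- trimws(substr(ln, m + 1, nchar(ln)))
    if (!nzchar(key)) stop("configuration line has an empty key: ", sQuote(ln))
    kv[[key]] <- val
  }
  kv
}

#' Read a parameter configuration file
#'
#' Parses the package's flat key-value configuration dialect (`key = value`,
#' `#` comments, blank lines ignored) into a validated parameter set. Keys
#' are the canonical quantity names (e.g. `c_ipc`, setting the point value)
#' or field-qualified forms `c_ipc.value`, `c_ipc.low`, `c_ipc.high`,
#' `c_ipc.family`, plus the scalars `wtp`, `n_psa`, `rng_seed`. Missing keys
#' fall back to the defaults of [default_parameters()]. Overriding only the
#' value of a quantity with an auto-derived range regenerates its +/-10%
#' range around the new value.
#'
#' @param path Path to the configuration file.
#' @return A validated `vte_params` object.
#' @seealso [write_parameters()] for the lossless inverse.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("cannot read configuration file: ", path)
  kv <- .parse_config_lines(readLines(path, warn = FALSE))
  params <- default_parameters()
  reg <- .vte_registry()
  known <- reg$key
  num <- function(key, val) {
    x <- suppressWarnings(as.numeric(val))
    if (is.na(x)) stop("non-numeric value for key ", sQuote(key), ": ", val,
                       call. = FALSE)
    x
  }
  touched <- new.env()
  for (key in names(kv)) {
    val <- kv[[key]]
    if (key %in% c("wtp", "n_psa", "rng_seed")) {
      params[[key]] <- num(key, val)
      next
    }
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    base <- parts[1]
    field <- if (length(parts) == 1) "value" else parts[2]
    if (!base %in% known || length(parts) > 2 ||
        !field %in% c("value", "low", "high", "family"))
      stop("unknown configuration key: ", sQuote(key), call. = FALSE)
    q <- params$quantities[[base]]
    if (field == "family") {
      if (!val %in% c("beta", "gamma", "lognormal", "fixed"))
        stop("invalid family for key ", sQuote(key), ": ", val, call. = FALSE)
      q$family <- val
    } else {
      q[[field]] <- num(key, val)
      if (field != "value") q$auto_range <- FALSE
    }
    params$quantities[[base]] <- q
    assign(base, union(get0(base, envir = touched, ifnotfound = character(0)),
                       field), envir = touched)
  }
  # regenerate auto ranges where only the value was overridden
  for (base in ls(touched)) {
    fields <- get(base, envir = touched)
    q <- params$quantities[[base]]
    if (identical(fields, "value") && isTRUE(q$auto_range)) {
      q$low <- 0.9 * q$value
      q$high <- 1.1 * q$value
      params$quantities[[base]] <- q
    }
  }
  validate_parameters(params)
  params
}

#' Write a parameter configuration file
#'
#' Serializes a parameter set to the flat key-value configuration dialect at
#' full double precision, so that `load_parameters(write_parameters(p, f))`
#' reproduces `p` field-for-field. The set is validated before writing;
#' an invalid set is refused.
#'
#' @param params A `vte_params` object.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  reg <- .vte_registry()
  lines <- c("# vtecea model parameter configuration",
             "# probabilities are fractions in [0,1]; costs in 2021 R$")
  for (key in reg$key) {
    q <- params$quantities[[key]]
    lines <- c(lines,
               sprintf("%s.value = %s", key, .fmt_num(q$value)),
               sprintf("%s.low = %s", key, .fmt_num(q$low)),
               sprintf("%s.high = %s", key, .fmt_num(q$high)),
               sprintf("%s.family = %s", key, q$family))
  }
  lines <- c(lines,
             sprintf("wtp = %s", .fmt_num(params$wtp)),
             sprintf("n_psa = %s", .fmt_num(params$n_psa)),
             sprintf("rng_seed = %s", .fmt_num(params$rng_seed)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @export
print.vte_params <- function(x, ...) {
  reg <- .vte_registry()
  cat("Cesarean-delivery thromboprophylaxis model parameters\n")
  cat(sprintf("  WTP: R$%s per AE avoided; PSA: %d draws (seed %d)\n",
              format(x$wtp, big.mark = ","), as.integer(x$n_psa),
              as.integer(x$rng_seed)))
  df <- data.frame(
    key = reg$key, kind = reg$kind,
    value = vapply(reg$key, function(k) x$quantities[[k]]$value, 0),
    low = vapply(reg$key, function(k) x$quantities[[k]]$low, 0),
    high = vapply(reg$key, function(k) x$quantities[[k]]$high, 0),
    family = vapply(reg$key, function(k) x$quantities[[k]]$family, ""),
    row.names = NULL)
  print(df, row.names = FALSE)
  invisible(x)
}
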