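#' Prophylaxis strategy specification
#'
#' Identifies one of the three compared thromboprophylaxis strategies and,
#' for IPC, the phase of use. IPC worn intra- and postoperatively is the base
#' case; the `intra_only` and `post_only` phases are the scenario-analysis
#' variants (intraoperative use reduces spinal-anesthesia hypotension,
#' postoperative use confers the VTE protection).
#'
#' @param name One of `"no_prophylaxis"`, `"IPC"`, `"LMWH"`.
#' @param phase One of `"intra_and_post"` (default), `"intra_only"`,
#'   `"post_only"`; phases other than the default are only meaningful for IPC.
#' @return An object of class `strategy_spec` with fields `name` and `phase`.
#' @export
strategy_spec <- function(name = c("no_prophylaxis", "IPC", "LMWH"),
                          phase = c("intra_and_post", "intra_only", "post_only")) {
  name <- match.arg(name)
  phase <- match.arg(phase)
  if (phase != "intra_and_post" && name != "IPC")
    stop("phase ", sQuote(phase), " is only meaningful for the IPC strategy")
  structure(list(name = name, phase = phase), class = "strategy_spec")
}

#' @export
print.strategy_spec <- function(x, ...) {
  lab <- x$name
  if (x$name == "IPC") lab <- paste0(lab, " (", gsub("_", " ", x$phase), ")")
  cat("strategy:", lab, "\n")
  invisible(x)
}

# Human-readable strategy label used in result tables.
.strategy_label <- function(spec) {
  if (spec$name == "IPC" && spec$phase != "intra_and_post")
    return(paste0("IPC_", spec$phase))
  spec$name
}

#' Resolve per-strategy event probabilities
#'
#' Applies the relative risks to the no-prophylaxis baseline incidences to
#' obtain the chance-node probabilities and prophylaxis cost for one
#' strategy:
#' \describe{
#'   \item{no prophylaxis}{baseline probabilities; no prophylaxis cost.}
#'   \item{LMWH}{DVT, minor-bleed and major-bleed baselines multiplied by the
#'     corresponding LMWH relative risks; hypotension at baseline; drug cost.}
#'   \item{IPC}{DVT risk chained through LMWH's relative risk and the
#'     IPC-vs-LMWH relative risk (the only composition available from the
#'     inputs); bleeding at baseline (mechanical prophylaxis carries no
#'     bleeding risk); hypotension baseline multiplied by the limb-compression
#'     relative risk; device cost. The `post_only` phase leaves hypotension
#'     at baseline; the `intra_only` phase leaves DVT at baseline.}
#' }
#' Every probability-times-relative-risk product is clamped to \[0,1\]; the
#' number of clamped products is attached as attribute `n_clamped` (relevant
#' for probabilistic draws at extreme sampled relative risks). The
#' PE-given-DVT probability is strategy-invariant.
#'
#' @param params A `vte_params` object.
#' @param strategy A [strategy_spec()] (or a strategy name).
#' @return An object of class `vte_event_probs`: list with `p_hypo`, `p_dvt`,
#'   `p_pe_given_dvt`, `p_minor`, `p_major`, `c_prophylaxis`, `strategy`.
#' @examples
#' p <- default_parameters()
#' resolve_strategy(p, "IPC")$p_hypo  # 0.6629 * 0.36 = 0.238644
#' @export
resolve_strategy <- function(params, strategy) {
  validate_parameters(params)
  .resolve_strategy_impl(params, strategy)
}

# Resolution without re-validation, for tight Monte Carlo loops where the
# draws are valid by construction.
.resolve_strategy_impl <- function(params, strategy) {
  if (is.character(strategy)) strategy <- strategy_spec(strategy)
  if (!inherits(strategy, "strategy_spec"))
    stop("'strategy' must be a strategy_spec or a strategy name")
  v <- function(k) .pv(params, k)
  n_clamped <- 0L
  clamp <- function(x) {
    if (x > 1 || x < 0) n_clamped <<- n_clamped + 1L
    min(max(x, 0), 1)
  }
  base <- list(p_hypo = v("p_hypo_baseline"), p_dvt = v("p_dvt_baseline"),
               p_minor = v("p_minor_baseline"), p_major = v("p_major_baseline"))
  out <- switch(strategy$name,
    no_prophylaxis = c(base, list(c_prophylaxis = 0)),
    LMWH = list(
      p_hypo = base$p_hypo,
      p_dvt = clamp(base$p_dvt * v("rr_lmwh_dvt")),
      p_minor = clamp(base$p_minor * v("rr_lmwh_minor")),
      p_major = clamp(base$p_major * v("rr_lmwh_major")),
      c_prophylaxis = v("c_lmwh")),
    IPC = {
      p_dvt <- if (strategy$phase == "intra_only") base$p_dvt
               else clamp(clamp(base$p_dvt * v("rr_lmwh_dvt")) *
                          v("rr_ipc_vs_lmwh_vte"))
      p_hypo <- if (strategy$phase == "post_only") base$p_hypo
                else clamp(base$p_hypo * v("rr_compression_hypo"))
      list(p_hypo = p_hypo, p_dvt = p_dvt, p_minor = base$p_minor,
           p_major = base$p_major, c_prophylaxis = v("c_ipc"))
    },
    stop("unknown strategy name: ", strategy$name))
  out$p_pe_given_dvt <- v("p_pe_given_dvt")
  structure(c(out, list(strategy = strategy)),
            class = "vte_event_probs", n_clamped = n_clamped)
}

#' Resolve all base-case strategies
#'
#' @param params A `vte_params` object.
#' @return A list of three `vte_event_probs` objects in the fixed order
#'   no prophylaxis, IPC (intra+post), LMWH.
#' @export
all_strategies <- function(params) {
  lapply(c("no_prophylaxis", "IPC", "LMWH"),
         function(nm) resolve_strategy(params, nm))
}
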