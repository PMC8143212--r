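#' Model variant for the nonselective-autophagy ATG13 pulse
#'
#' Six variants describe the single ATG13 accumulation/removal pulse.
#' Variants 1-3 are event-based: accumulation runs on `[0, t)` and a discrete
#' event at time `t` switches the system to removal. Variants 4-6 are
#' eventless: accumulation and removal act simultaneously at all times.
#' Wortmannin down-regulates accumulation (variants 1 and 4), removal
#' (2 and 5) or both reactions (3 and 6) by the multiplicative factor
#' `kwrtm`.
#'
#' @param variant_id Integer in 1..6.
#' @return An object of class `model_variant` with fields `variant_id`,
#'   `event_based` and `wortmannin_target`
#'   (one of `"accumulation"`, `"removal"`, `"both"`).
#' @export
#' @examples
#' model_variant(3)
model_variant <- function(variant_id) {
  if (length(variant_id) != 1L || !is.finite(variant_id) ||
      variant_id != round(variant_id) || variant_id < 1 || variant_id > 6) {
    stop("variant_id must be a single integer in 1..6")
  }
  variant_id <- as.integer(variant_id)
  target <- c("accumulation", "removal", "both")[((variant_id - 1L) %% 3L) + 1L]
  structure(
    list(
      variant_id = variant_id,
      event_based = variant_id <= 3L,
      wortmannin_target = target
    ),
    class = "model_variant"
  )
}

#' @export
print.model_variant <- function(x, ...) {
  cat(sprintf(
    "ATG13 model variant %d: %s, wortmannin targets %s\n",
    x$variant_id, if (x$event_based) "event-based" else "eventless",
    x$wortmannin_target
  ))
  invisible(x)
}

#' Parameter set for the nonselective ATG13 pulse models
#'
#' @param kprodATG13 Accumulation rate constant (AU^(1-m)/s).
#' @param kremATG13 Removal rate constant (1/s).
#' @param m Partial reaction order of aggregated ATG13 in the accumulation
#'   rate law (dimensionless, >= 0). Captures the cooperativity of ULK-complex
#'   aggregation on the already aggregated ATG13 pool.
#' @param kwrtm Wortmannin multiplicative down-regulation factor in (0, 1].
#' @param t Event time from initiation to the accumulation-to-removal switch
#'   (s). Only used by event-based variants; may be `NA` for variants 4-6.
#' @param atg13_seed Initial aggregated ATG13 (AU, small > 0). Required
#'   because A(0) = 0 with m > 0 stalls the aggregation feedback entirely.
#' @param removal_order Exponent of A in the removal law. Default 1
#'   (first-order mass action); set to `1 + m` to explore the alternative
#'   reading in which disappearance shares the partial order.
#' @return An object of class `nonselective_params`.
#' @export
nonselective_params <- function(kprodATG13, kremATG13, m, kwrtm = 1,
                                t = NA_real_, atg13_seed = 0.01,
                                removal_order = 1) {
  stopifnot(
    kprodATG13 >= 0, kremATG13 >= 0, m >= 0,
    kwrtm > 0, kwrtm <= 1,
    is.na(t) || t > 0,
    atg13_seed > 0,
    removal_order >= 0
  )
  structure(
    list(
      kprodATG13 = kprodATG13, kremATG13 = kremATG13, m = m,
      kwrtm = kwrtm, t = t, atg13_seed = atg13_seed,
      removal_order = removal_order
    ),
    class = "nonselective_params"
  )
}

#' Published best-fit parameter set for the nonselective pulse
#'
#' Rate constants and partial order are the study's best fit for the
#' event-based variant with wortmannin acting on both reactions. The
#' wortmannin factor and event time were not printed and carry package
#' defaults chosen to reproduce the qualitative pulse behavior (see the
#' methods vignette).
#'
#' @param ... Overrides passed to [nonselective_params()].
#' @return A `nonselective_params` object.
#' @export
default_nonselective_params <- function(...) {
  defaults <- list(
    kprodATG13 = 0.0082, kremATG13 = 0.0029, m = 1.01365,
    kwrtm = 0.4, t = 300, atg13_seed = 0.01
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(nonselective_params, args)
}

#' Parameter set for the hybrid mitophagy oscillation model
#'
#' Extends the nonselective pulse with cumulative LC3 deposition and a
#' cycle-indexed delay law. Each aggregation cycle k accumulates ATG13 for a
#' (sampled) time-to-peak, removes it back to baseline, deposits LC3 in
#' proportion to the ATG13 time integral, then waits `kpeak * k^p` seconds
#' before the next cycle. Engulfment completes when cumulative LC3 reaches
#' `engulf_coeff * mt_diam`.
#'
#' @param kprodATG13,kremATG13,m As in [nonselective_params()].
#' @param kprodLC3 LC3 production rate driven by aggregated ATG13
#'   (AU/s per AU ATG13).
#' @param kpeak Base inter-aggregation delay coefficient (s).
#' @param p Delay growth exponent (dimensionless >= 0); the delay before
#'   cycle k+1 is `kpeak * k^p`.
#' @param Tau Lag before cumulative LC3 inhibits a new ATG13 accumulation (s).
#' @param t_mean,t_sd Normal distribution of per-cycle time-to-peak (s).
#' @param mt_diam_mean,mt_diam_sd Normal distribution of mitochondrial
#'   fragment diameters (micrometres).
#' @param engulf_coeff LC3 amount required per micrometre of diameter for
#'   full engulfment (AU per micrometre).
#' @param atg13_seed Baseline aggregated ATG13 at cycle start (AU > 0).
#' @param area_threshold If `TRUE`, the engulfment threshold scales with
#'   `mt_diam^2` (surface-area reading) instead of linearly with diameter.
#' @return An object of class `mitophagy_params`.
#' @export
mitophagy_params <- function(kprodATG13, kremATG13, m, kprodLC3, kpeak, p,
                             Tau = 0, t_mean, t_sd, mt_diam_mean, mt_diam_sd,
                             engulf_coeff, atg13_seed = 0.01,
                             area_threshold = FALSE) {
  stopifnot(
    kprodATG13 >= 0, kremATG13 >= 0, m >= 0, kprodLC3 >= 0,
    kpeak >= 0, p >= 0, Tau >= 0,
    t_mean > 0, t_sd >= 0, mt_diam_mean > 0, mt_diam_sd >= 0,
    engulf_coeff > 0, atg13_seed > 0
  )
  structure(
    list(
      kprodATG13 = kprodATG13, kremATG13 = kremATG13, m = m,
      kprodLC3 = kprodLC3, kpeak = kpeak, p = p, Tau = Tau,
      t_mean = t_mean, t_sd = t_sd,
      mt_diam_mean = mt_diam_mean, mt_diam_sd = mt_diam_sd,
      engulf_coeff = engulf_coeff, atg13_seed = atg13_seed,
      area_threshold = isTRUE(area_threshold)
    ),
    class = "mitophagy_params"
  )
}

#' Published best-fit parameter set for the mitophagy model
#'
#' ATG13 rate constants and the delay exponent are the study's printed fits
#' (kprodATG13 = kremATG13 = 0.0114, p ~ 2.79). Remaining quantities were not
#' printed; package defaults reproduce roughly six aggregation cycles at the
#' mean diameter with the final removal ending near 910 s (methods vignette).
#'
#' @param ... Overrides passed to [mitophagy_params()].
#' @return A `mitophagy_params` object.
#' @export
default_mitophagy_params <- function(...) {
  defaults <- list(
    kprodATG13 = 0.0114, kremATG13 = 0.0114, m = 1.01365,
    kprodLC3 = 0.01, kpeak = 0.9, p = 2.79, Tau = 0,
    t_mean = 45, t_sd = 9, mt_diam_mean = 0.9, mt_diam_sd = 0.25,
    engulf_coeff = 0.07, atg13_seed = 0.01
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(mitophagy_params, args)
}

wortmannin_scales <- function(params, wortmannin_active, variant) {
  acc <- 1
  rem <- 1
  if (isTRUE(wortmannin_active)) {
    if (variant$wortmannin_target %in% c("accumulation", "both")) acc <- params$kwrtm
    if (variant$wortmannin_target %in% c("removal", "both")) rem <- params$kwrtm
  }
  list(acc = acc, rem = rem)
}

#' ATG13 accumulation rate
#'
#' `kprodATG13 * A^m`, down-regulated by `kwrtm` when wortmannin is active
#' and the variant targets accumulation (or both reactions).
#'
#' @param A Aggregated ATG13 (AU, >= 0); vectorized.
#' @param params A `nonselective_params` (or `mitophagy_params` with
#'   `kwrtm = 1` semantics, i.e. no wortmannin arm).
#' @param wortmannin_active Logical flag for the wortmannin condition.
#' @param variant A `model_variant`.
#' @return Accumulation rate (AU/s).
#' @export
rate_accumulation <- function(A, params, wortmannin_active = FALSE,
                              variant = model_variant(3)) {
  if (any(!is.finite(A)) || any(A < 0)) stop("A must be finite and >= 0")
  sc <- wortmannin_scales(params, wortmannin_active, variant)
  r <- sc$acc * params$kprodATG13 * A^params$m
  # 0^0 = 1 in R is the wanted zeroth-order limit; A=0 with m>0 gives 0
  r
}

#' ATG13 removal rate
#'
#' First-order mass action `kremATG13 * A` by default (the exponent follows
#' `params$removal_order`), down-regulated by `kwrtm` when wortmannin is
#' active and the variant targets removal (or both reactions).
#'
#' @inheritParams rate_accumulation
#' @return Removal rate (AU/s).
#' @export
rate_removal <- function(A, params, wortmannin_active = FALSE,
                         variant = model_variant(3)) {
  if (any(!is.finite(A)) || any(A < 0)) stop("A must be finite and >= 0")
  sc <- wortmannin_scales(params, wortmannin_active, variant)
  ord <- if (is.null(params$removal_order)) 1 else params$removal_order
  sc$rem * params$kremATG13 * A^ord
}

#' Serialize a parameter set or model variant to JSON
#'
#' Field names in the JSON match the parameter names exactly; a variant is
#' stored by its integer id so the mapping round-trips.
#'
#' @param x A `nonselective_params`, `mitophagy_params` or `model_variant`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
params_to_json <- function(x, path = NULL) {
  payload <- if (inherits(x, "model_variant")) {
    list(type = "model_variant", variant_id = x$variant_id)
  } else if (inherits(x, "nonselective_params")) {
    c(list(type = "nonselective_params"), unclass(x))
  } else if (inherits(x, "mitophagy_params")) {
    c(list(type = "mitophagy_params"), unclass(x))
  } else {
    stop("unsupported object for JSON serialization")
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Deserialize a parameter set or model variant from JSON
#'
#' @param json JSON string or path to a JSON file written by
#'   [params_to_json()].
#' @return The reconstructed object.
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  type <- x$type
  x$type <- NULL
  switch(type,
    model_variant = model_variant(x$variant_id),
    nonselective_params = do.call(nonselective_params, x),
    mitophagy_params = do.call(mitophagy_params, x),
    stop("unknown serialized type: ", type)
  )
}
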