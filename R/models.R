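#' Temperature-dependent aragonite-water fractionation model
#'
#' Represents a fractionation relation of the standard palaeothermometric
#' form \deqn{1000 \ln \alpha = a \cdot 1000 / T + b} where
#' \eqn{\alpha = (1000 + \delta_o) / (1000 + \delta_w)} is the
#' aragonite-water fractionation factor, T is temperature in Kelvin, `a` is
#' in per-mil Kelvin and `b` in per mil. Because `a > 0`, fractionation (and
#' hence the predicted otolith value) decreases with temperature.
#'
#' Two models ship in the registry (see [get_fractionation_model()]):
#' `"kim-aragonite"`, the laboratory relation for inorganic aragonite
#' deposition (a = 17.88, b = -31.14), and `"geffen-plaice"`, a relation of
#' the juvenile-fish rearing type with a shallower temperature dependence
#' (a = 16.75, b = -27.09). The plaice coefficients are representative
#' stand-in values of the published biogenic form, documented as such, since
#' the exact experimental coefficients could not be verified offline.
#'
#' @param name label used in provenance and error messages.
#' @param a slope coefficient of the 1000/T term, per-mil Kelvin; must be > 0.
#' @param b intercept, per mil.
#' @param valid_T_range length-2 numeric, Kelvin; evaluation outside it
#'   warns (the relation extrapolates smoothly) but does not error.
#' @return an object of class `fractionation_model`.
#' @export
fractionation_model <- function(name, a, b,
                                valid_T_range = c(273.15, 313.15)) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(a) || length(a) != 1L || a <= 0) {
    stop_input("fractionation coefficient 'a' must be a positive scalar")
  }
  stopifnot(is.numeric(b), length(b) == 1L,
            is.numeric(valid_T_range), length(valid_T_range) == 2L,
            valid_T_range[1] < valid_T_range[2], valid_T_range[1] > 0)
  structure(list(name = name, a = a, b = b,
                 valid_T_range = as.numeric(valid_T_range)),
            class = "fractionation_model")
}

#' @export
print.fractionation_model <- function(x, ...) {
  cat(sprintf(
    "<fractionation_model> %s: 1000 ln a = %.2f * 1000/T %+.2f  (valid %.1f-%.1f K)\n",
    x$name, x$a, x$b, x$valid_T_range[1], x$valid_T_range[2]))
  invisible(x)
}

#' Linear seawater d18O-salinity mixing relation
#'
#' \eqn{\delta^{18}O_w (VSMOW) = slope \cdot S + intercept}. The slope is
#' positive: fresher water carries isotopically lighter oxygen because the
#' freshwater end-member is strongly depleted.
#'
#' @param name label; `"northsea-mixing"` and `"natl-mixing"` ship in the
#'   registry.
#' @param slope per mil per salinity unit, must be > 0.
#' @param intercept per mil (VSMOW).
#' @param region free-text provenance.
#' @return an object of class `water_mixing_relation`.
#' @export
water_mixing_relation <- function(name, slope, intercept, region = "") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0) {
    stop_input("mixing-relation slope must be a positive scalar")
  }
  stopifnot(is.numeric(intercept), length(intercept) == 1L)
  structure(list(name = name, slope = slope, intercept = intercept,
                 region = region),
            class = "water_mixing_relation")
}

#' @export
print.water_mixing_relation <- function(x, ...) {
  cat(sprintf("<water_mixing_relation> %s (%s): d18Ow = %.3f * S %+.3f (VSMOW)\n",
              x$name, x$region, x$slope, x$intercept))
  invisible(x)
}

# ---- model registry ---------------------------------------------------------

.otoscape_registry <- new.env(parent = emptyenv())

load_model_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "isotope_models.json", package = "otoscape")
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  frac <- lapply(cfg$fractionation_models, function(m) {
    fractionation_model(m$name, m$a, m$b, unlist(m$valid_T_range_K))
  })
  names(frac) <- vapply(frac, `[[`, "", "name")
  mix <- lapply(cfg$mixing_relations, function(m) {
    water_mixing_relation(m$name, m$slope, m$intercept, m$region %||% "")
  })
  names(mix) <- vapply(mix, `[[`, "", "name")
  assign("fractionation", frac, envir = .otoscape_registry)
  assign("mixing", mix, envir = .otoscape_registry)
  invisible(list(fractionation = frac, mixing = mix))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

registry_get <- function(kind, name) {
  if (!exists(kind, envir = .otoscape_registry)) load_model_registry()
  reg <- get(kind, envir = .otoscape_registry)
  if (!name %in% names(reg)) {
    stop_input("unknown %s '%s'; registered: %s", kind, name,
               paste(names(reg), collapse = ", "))
  }
  reg[[name]]
}

#' Look up a registered fractionation model or mixing relation by name
#'
#' The registry is read from the JSON configuration shipped with the
#' package (`extdata/isotope_models.json`); user-supplied models with the
#' same schema can be registered by calling [register_models()] on another
#' JSON file, or constructed directly with [fractionation_model()] /
#' [water_mixing_relation()] and passed wherever a model is accepted.
#'
#' @param name registry key, e.g. `"kim-aragonite"` or `"northsea-mixing"`.
#' @return the model object.
#' @export
get_fractionation_model <- function(name) registry_get("fractionation", name)

#' @rdname get_fractionation_model
#' @export
get_mixing_relation <- function(name) registry_get("mixing", name)

#' @rdname get_fractionation_model
#' @param path JSON file with `fractionation_models` / `mixing_relations`
#'   arrays following the shipped schema.
#' @export
register_models <- function(path) load_model_registry(path)

as_fractionation_model <- function(model) {
  if (inherits(model, "fractionation_model")) return(model)
  if (is.character(model) && length(model) == 1L) {
    return(get_fractionation_model(model))
  }
  stop_input("expected a fractionation_model or a registry name")
}

as_mixing_relation <- function(relation) {
  if (inherits(relation, "water_mixing_relation")) return(relation)
  if (is.character(relation) && length(relation) == 1L) {
    return(get_mixing_relation(relation))
  }
  stop_input("expected a water_mixing_relation or a registry name")
}

# ---- core predictions -------------------------------------------------------

#' Predict water d18O from salinity
#'
#' Applies the linear mixing relation; output is a water [delta_value()] on
#' the VSMOW scale.
#'
#' @param S salinity (practical salinity units), in `[0, 40]`.
#' @param relation a [water_mixing_relation()] or registry name
#'   (default `"northsea-mixing"`).
#' @return water `delta_value` (VSMOW).
#' @export
salinity_to_water_d18O <- function(S, relation = "northsea-mixing") {
  relation <- as_mixing_relation(relation)
  if (any(!is.finite(S)) || any(S < 0) || any(S > 40)) {
    stop_input("salinity must lie in [0, 40]")
  }
  delta_value(relation$slope * S + relation$intercept, "VSMOW", "water")
}

celsius_to_kelvin <- function(t_c) t_c + 273.15
kelvin_to_celsius <- function(t_k) t_k - 273.15

check_T_validity <- function(T_kelvin, model) {
  r <- model$valid_T_range
  if (any(T_kelvin < r[1] | T_kelvin > r[2])) {
    warning(sprintf(
      "temperature outside validity range [%.1f, %.1f] K of model '%s'",
      r[1], r[2], model$name), call. = FALSE)
  }
}

#' Predict otolith d18O from temperature and water d18O
#'
#' Solves the fractionation relation
#' \eqn{1000\ln\alpha = a\,1000/T + b} for the otolith value given the
#' water value: \eqn{\delta_o = \alpha (1000 + \delta_w) - 1000}. Following
#' the pipeline order this package standardises on, the water delta is
#' expected on the VPDB scale (salinity -> VSMOW via the mixing relation ->
#' VPDB via [convert_scale()] -> fractionation), and the result is an
#' otolith delta on VPDB. The prediction is strictly decreasing in
#' temperature.
#'
#' @param T_kelvin temperature(s) in Kelvin, > 0.
#' @param d18Ow water delta: a `delta_value` (converted to VPDB if needed)
#'   or a plain numeric taken to be VPDB per mil.
#' @param model a [fractionation_model()] or registry name
#'   (default `"kim-aragonite"`).
#' @return otolith `delta_value` (VPDB).
#' @export
predict_otolith_d18O <- function(T_kelvin, d18Ow, model = "kim-aragonite") {
  model <- as_fractionation_model(model)
  if (any(!is.finite(T_kelvin)) || any(T_kelvin <= 0)) {
    stop_input("temperature must be positive (Kelvin)")
  }
  check_T_validity(T_kelvin, model)
  dw <- if (is_delta(d18Ow)) {
    if (d18Ow$scale != "VPDB") {
      delta_num(convert_scale(d18Ow, "VPDB"))
    } else d18Ow$value
  } else as.numeric(d18Ow)
  alpha <- exp((model$a * 1000 / T_kelvin + model$b) / 1000)
  delta_value(alpha * (1000 + dw) - 1000, "VPDB", "otolith")
}

#' Invert the fractionation relation for temperature
#'
#' Closed-form inverse of [predict_otolith_d18O()]: given otolith and water
#' deltas on the same scale, returns the unique temperature (Kelvin)
#' satisfying the model. A bisection fallback guards coefficient sets for
#' which the closed form degenerates (log-argument or denominator not
#' positive).
#'
#' @param d18Oo,d18Ow otolith and water deltas, `delta_value`s or numerics
#'   on a common scale (VPDB assumed for numerics).
#' @param model a [fractionation_model()] or registry name.
#' @return temperature(s) in Kelvin.
#' @export
invert_temperature <- function(d18Oo, d18Ow, model = "kim-aragonite") {
  model <- as_fractionation_model(model)
  do_ <- delta_num(d18Oo)
  dw <- delta_num(d18Ow)
  if (is_delta(d18Oo) && is_delta(d18Ow) && d18Oo$scale != d18Ow$scale) {
    stop_input("otolith and water deltas must be on the same scale")
  }
  ratio <- (1000 + do_) / (1000 + dw)
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop_input("no physical solution: fractionation factor not positive")
  }
  denom <- 1000 * log(ratio) - model$b
  t_k <- ifelse(denom > 0, model$a * 1000 / denom, NA_real_)
  if (any(is.na(t_k))) {
    # bisection fallback over a generous bracket
    f <- function(T, i) {
      delta_num(predict_otolith_d18O(T, dw[i], model)) - do_[i]
    }
    for (i in which(is.na(t_k))) {
      lo <- 150; hi <- 500
      if (f(lo, i) * f(hi, i) > 0) {
        stop_input("no temperature solution with T > 0 for sample %d", i)
      }
      t_k[i] <- stats::uniroot(f, c(lo, hi), i = i, tol = 1e-9)$root
    }
  }
  if (any(t_k <= 0)) stop_input("no temperature solution with T > 0")
  t_k
}

#' Temperature bias induced by a salinity perturbation
#'
#' Sensitivity analysis for the full prediction chain: at a reference
#' temperature and salinity, the "true" otolith value is computed through
#' mixing relation -> scale conversion -> fractionation. Salinity is then
#' perturbed by `dS`, the water delta recomputed, and the fractionation
#' relation re-inverted for temperature while holding the otolith value
#' fixed. The returned value is the absolute temperature shift in degrees
#' Celsius per `dS` salinity units: the error a temperature reconstruction
#' would incur from a salinity mis-specification of `dS`.
#'
#' @param relation mixing relation or registry name.
#' @param model fractionation model or registry name.
#' @param T_ref_kelvin reference temperature, Kelvin (default 283.15 K,
#'   i.e. 10 degrees C, typical North Sea bottom water).
#' @param S_ref reference salinity (default 35).
#' @param dS salinity perturbation, non-zero (default +1).
#' @return absolute temperature shift, degrees Celsius.
#' @examples
#' temperature_bias_per_salinity() # about 1.3 degC for the North Sea chain
#' @export
temperature_bias_per_salinity <- function(relation = "northsea-mixing",
                                          model = "kim-aragonite",
                                          T_ref_kelvin = 283.15,
                                          S_ref = 35, dS = 1) {
  if (!is.numeric(dS) || length(dS) != 1L) stop_input("dS must be a scalar")
  if (dS == 0) return(0)
  relation <- as_mixing_relation(relation)
  model <- as_fractionation_model(model)
  dw_ref <- convert_scale(salinity_to_water_d18O(S_ref, relation), "VPDB")
  do_true <- predict_otolith_d18O(T_ref_kelvin, dw_ref, model)
  dw_pert <- convert_scale(salinity_to_water_d18O(S_ref + dS, relation), "VPDB")
  t_new <- invert_temperature(do_true, dw_pert, model)
  abs(t_new - T_ref_kelvin)
}

#' Temperature difference equivalent to an otolith d18O difference
#'
#' How many degrees Celsius of (re-inverted) temperature correspond to a
#' given otolith delta difference under a fractionation model, at fixed
#' water composition. Used to express measurement-level or vital-effect
#' offsets in thermometric units.
#'
#' @param d_delta otolith delta difference, per mil (default -0.5: the
#'   otolith value drops by half a per mil).
#' @param model fractionation model or registry name.
#' @param T_start_kelvin starting temperature, Kelvin (default 285.65 K =
#'   12.5 degrees C, the middle of the 10-15 degrees C window).
#' @param S_ref,relation water composition via salinity and mixing relation.
#' @return absolute temperature difference, degrees Celsius.
#' @examples
#' delta_temperature_equivalent(-0.5) # about 2.3 degC
#' @export
delta_temperature_equivalent <- function(d_delta = -0.5,
                                         model = "kim-aragonite",
                                         T_start_kelvin = 285.65,
                                         S_ref = 35,
                                         relation = "northsea-mixing") {
  model <- as_fractionation_model(model)
  dw <- convert_scale(salinity_to_water_d18O(S_ref, relation), "VPDB")
  do_start <- predict_otolith_d18O(T_start_kelvin, dw, model)
  do_new <- delta_value(do_start$value + d_delta, "VPDB", "otolith")
  abs(invert_temperature(do_new, dw, model) - T_start_kelvin)
}
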