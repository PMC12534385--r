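# YAML interfaces: battery designs and model specifications.

#' Write / read a battery design as YAML
#'
#' A design is the (f0, n_min, N) cell grid from which
#' \code{\link{build_battery}} constructs the paired test battery.
#'
#' @param design design data.frame (see
#'   \code{\link{default_battery_design}}).
#' @param path file path.
#' @return \code{path} (write) or the design data.frame (read).
#' @export
write_battery_design_yaml <- function(design, path) {
  stopifnot(all(c("f0_hz", "n_min", "n_harmonics") %in% names(design)))
  # f0 as %.17g strings: YAML numeric emission truncates doubles, and the
  # battery manifest must round-trip bit-exactly
  yaml::write_yaml(list(f0_hz = sprintf("%.17g", design$f0_hz),
                        n_min = design$n_min,
                        n_harmonics = design$n_harmonics), path)
  invisible(path)
}

#' @rdname write_battery_design_yaml
#' @export
read_battery_design_yaml <- function(path) {
  v <- yaml::read_yaml(path)
  out <- data.frame(f0_hz = as.numeric(unlist(v$f0_hz)),
                    n_min = as.integer(unlist(v$n_min)),
                    n_harmonics = as.integer(unlist(v$n_harmonics)))
  if (!nrow(out)) stop("empty battery design")
  out
}

#' Write / read a model specification as YAML
#'
#' Serializes the family, the term lists (fixed, smooth, monotonic, random)
#' and the prior set.
#'
#' @param spec a \code{\link{model_spec}}.
#' @param path file path.
#' @return \code{path} (write) or a \code{model_spec} (read).
#' @export
write_model_spec_yaml <- function(spec, path) {
  out <- list(
    family = spec$family, response = spec$response, trials = spec$trials,
    se = spec$se, fixed = as.list(spec$fixed),
    smooths = lapply(spec$smooths, function(s)
      list(var = s$var, k = s$k,
           by = if (is.null(s$by)) NULL else as.list(s$by))),
    monotonic = as.list(spec$monotonic),
    random = if (is.null(spec$random)) NULL else
      list(group = spec$random$group, terms = as.list(spec$random$terms),
           correlated = spec$random$correlated),
    factors = as.list(spec$factors),
    priors = Filter(Negate(is.null), unclass(spec$priors)))
  yaml::write_yaml(Filter(Negate(is.null), out), path)
  invisible(path)
}

#' @rdname write_model_spec_yaml
#' @export
read_model_spec_yaml <- function(path) {
  v <- yaml::read_yaml(path)
  model_spec(
    family = v$family, response = v$response,
    fixed = as.character(unlist(v$fixed)),
    trials = v$trials, se = v$se,
    smooths = lapply(v$smooths, function(s)
      smooth_term(s$var, k = s$k,
                  by = if (is.null(s$by)) NULL else as.character(unlist(s$by)))),
    monotonic = as.character(unlist(v$monotonic)),
    random = if (is.null(v$random)) NULL else
      random_term(v$random$group, as.character(unlist(v$random$terms)),
                  isTRUE(v$random$correlated)),
    factors = as.character(unlist(v$factors)),
    priors = do.call(prior_set, v$priors))
}
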