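#' Serialize and restore system specifications
#'
#' Specs serialize to a canonical JSON document with top-level keys
#' `components`, `terms`, `parameters`, `initial_values`, `forcing`,
#' `nonneg_clip`, `variant`. Serialization is canonical: writing a spec,
#' reading it back, and writing it again produces byte-identical text
#' (numbers are emitted with 17 significant digits, which round-trips
#' doubles exactly).
#'
#' @param spec A `facsim_spec`.
#' @param path File path; `spec_to_json()` returns the JSON text instead.
#' @return `read_spec()` returns a `facsim_spec`; `write_spec()` returns
#'   `path` invisibly.
#' @export
spec_to_json <- function(spec) {
  comp <- lapply(spec$components, function(co) {
    list(name = co$name, label = co$label, role = co$role,
         initial_value = co$initial_value,
         lower_bound = if (is.na(co$lower_bound)) NULL else co$lower_bound,
         upper_bound = if (is.na(co$upper_bound)) NULL else co$upper_bound)
  })
  terms <- lapply(spec$terms, function(tm) {
    list(target = tm$target, form = tm$form, sources = as.list(tm$sources),
         coefficient = tm$coefficient, sign = tm$sign,
         modulators = lapply(tm$modulators, function(m)
           list(source = m$source, gain = m$gain, sign = m$sign)))
  })
  pv <- spec$parameters$values
  params <- lapply(seq_along(pv), function(i)
    list(name = names(pv)[i], value = unname(pv[i]),
         provenance = unname(spec$parameters$provenance[i])))
  forcing <- lapply(spec$forcings, function(f) unclass(f))
  doc <- list(components = comp, terms = terms, parameters = params,
              initial_values = as.list(initial_state(spec)),
              forcing = forcing,
              nonneg_clip = spec$nonneg_clip,
              variant = if (is.na(spec$variant)) NULL else spec$variant)
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                                pretty = TRUE, null = "null"))
}

#' @rdname spec_to_json
#' @export
write_spec <- function(spec, path) {
  writeLines(spec_to_json(spec), path)
  invisible(path)
}

#' @rdname spec_to_json
#' @export
read_spec <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  spec_from_list(doc)
}

num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

#' Rebuild a spec from its serialized (list) form
#' @param doc List as produced by parsing the JSON document.
#' @return A `facsim_spec`.
#' @keywords internal
#' @export
spec_from_list <- function(doc) {
  comps <- lapply(doc$components, function(co)
    component(co$name, co$label, co$role, co$initial_value,
              num_or_na(co$lower_bound), num_or_na(co$upper_bound)))
  terms <- lapply(doc$terms, function(tm)
    term(tm$target, tm$form, unlist(tm$sources), tm$coefficient, tm$sign,
         tm$modulators))
  vals <- vapply(doc$parameters, function(p) as.numeric(p$value), 0)
  names(vals) <- vapply(doc$parameters, function(p) p$name, "")
  prov <- vapply(doc$parameters, function(p) p$provenance, "")
  params <- parameter_set(vals, stats::setNames(prov, names(vals)))
  forcings <- lapply(doc$forcing, function(f) {
    switch(f$kind,
      constant = forcing_constant(f$level),
      pulses = forcing_pulses(f$level, unlist(f$onsets), unlist(f$offsets)),
      piecewise = forcing_piecewise(data.frame(time = unlist(f$times),
                                               level = unlist(f$levels))),
      stop("unknown forcing kind: ", f$kind))
  })
  spec <- system_spec(comps, terms, params, forcings,
                      nonneg_clip = isTRUE(doc$nonneg_clip),
                      variant = if (is.null(doc$variant)) NA_character_
                                else doc$variant)
  if (!is.null(doc$initial_values)) {
    iv <- doc$initial_values
    nm <- component_names(spec)
    for (k in names(iv)) {
      i <- match(k, nm)
      if (is.na(i)) stop("initial value for unknown component: ", k)
      spec$components[[i]]$initial_value <- as.numeric(iv[[k]])
    }
  }
  spec
}

#' Short content hash of a spec (run metadata)
#'
#' FNV-1a over the canonical JSON; stable across sessions, used only to
#' tag trajectories with the spec they came from.
#' @param spec A `facsim_spec`.
#' @return 8-hex-digit string.
#' @export
spec_hash <- function(spec) {
  bytes <- utf8ToInt(spec_to_json(spec))
  h <- 2166136261
  for (b in bytes) {
    # xor into the low byte (h can exceed .Machine$integer.max)
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    # 32-bit FNV prime multiply; split so intermediates stay exact doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
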