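.ocr_phases <- c("substrate", "adp", "oligomycin", "fccp", "rot_aa")

# phase-to-state map: substrate-only (State 2), ADP-stimulated ATP-linked
# respiration (State 3), oligomycin-inhibited proton leak (State 4o),
# FCCP-uncoupled maximal respiration (State 3u)
.state_of_phase <- c(substrate = "state2", adp = "state3",
                     oligomycin = "state4o", fccp = "state3u")

#' Respiration states from one well's OCR trace
#'
#' Summarizes each injection phase by the mean of its measurement cycles,
#' subtracts the non-mitochondrial rate (the residual after rotenone +
#' antimycin A) from every state, and normalizes by the well's protein
#' mass. Negative corrected states are clamped to 0 and flagged: negative
#' respiration is physically meaningless, but the flag preserves
#' auditability.
#'
#' @param trace data.frame for a single well: `cycle`, `phase` (one of
#'   substrate, adp, oligomycin, fccp, rot_aa, in that injection order),
#'   `ocr` (pmol O2/min), `protein_ug` (> 0, constant within the well).
#' @param subtract_nonmito subtract the rot_aa rate before normalizing
#'   (default TRUE, the standard treatment for isolated mitochondria).
#' @return one-row data.frame: `state2`, `state3`, `state4o`, `state3u`
#'   (pmol O2/min/ug protein), `nonmito`, `clamped` flag.
#' @export
compute_states <- function(trace, subtract_nonmito = TRUE) {
  stopifnot(is.data.frame(trace))
  miss <- setdiff(.ocr_phases, unique(as.character(trace$phase)))
  if (length(miss) > 0) stop("missing injection phase: ", miss[1])
  protein <- unique(trace$protein_ug)
  if (length(protein) != 1 || protein <= 0) {
    stop("protein_ug must be a single positive value per well")
  }
  first_cycle <- tapply(trace$cycle, factor(trace$phase, .ocr_phases), min)
  if (is.unsorted(first_cycle, strictly = TRUE)) {
    stop("phases out of order: expected substrate -> adp -> oligomycin -> fccp -> rot_aa")
  }
  ph_mean <- tapply(trace$ocr, factor(trace$phase, .ocr_phases), mean)
  nonmito <- if (subtract_nonmito) ph_mean[["rot_aa"]] else 0
  raw <- ph_mean[names(.state_of_phase)] - nonmito
  clamped <- any(raw < 0)
  states <- pmax(raw, 0) / protein
  out <- as.data.frame(as.list(stats::setNames(states, .state_of_phase)))
  out$nonmito <- nonmito / protein
  out$clamped <- clamped
  out
}

#' Respiratory control ratio
#'
#' State 3 (ADP-stimulated) over State 4o (oligomycin-inhibited proton
#' leak): the coupling between substrate oxidation and ATP synthesis.
#' Undefined (NA, flagged) when State 4o is not positive.
#'
#' @param state3,state4o respiration states, same length.
#' @return numeric RCR with a logical `undefined` attribute.
#' @export
rcr <- function(state3, state4o) {
  undef <- !(state4o > 0)
  out <- ifelse(undef, NA_real_, state3 / state4o)
  attr(out, "undefined") <- undef
  out
}

#' Per-mouse respiration states from a multi-well OCR table
#'
#' Computes per-well states (see [compute_states()]) and averages the
#' quintuplicate wells for each mouse x substrate. RCR is computed per
#' well and then averaged ("per_well", respecting the within-well pairing)
#' or as the ratio of the averaged states ("of_means").
#'
#' @param ocr tidy data.frame: `well_id`, `mouse_id`, `substrate`
#'   (pyruvate_malate or succinate_rotenone), `cycle`, `phase`, `ocr`,
#'   `protein_ug`.
#' @param subtract_nonmito see [compute_states()].
#' @param rcr_method "per_well" (default) or "of_means".
#' @return data.frame per mouse x substrate: states, `rcr`, `n_wells`,
#'   `any_clamped`.
#' @export
ocr_states <- function(ocr, subtract_nonmito = TRUE,
                       rcr_method = c("per_well", "of_means")) {
  rcr_method <- match.arg(rcr_method)
  need <- c("well_id", "mouse_id", "substrate", "cycle", "phase", "ocr",
            "protein_ug")
  miss <- setdiff(need, names(ocr))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  wells <- split(ocr, ocr$well_id)
  per_well <- do.call(rbind, lapply(wells, function(w) {
    st <- compute_states(w, subtract_nonmito)
    st$well_id <- w$well_id[1]
    st$mouse_id <- w$mouse_id[1]
    st$substrate <- w$substrate[1]
    st$rcr <- as.numeric(rcr(st$state3, st$state4o))
    st
  }))
  aggregate_mouse(per_well, rcr_method)
}

#' Average per-well respiration states within mouse
#'
#' Arithmetic mean of each state over a mouse's wells (measurements are
#' run in quintuplicate and averaged per mouse), separately per substrate.
#'
#' @param per_well data.frame of per-well states with `mouse_id`,
#'   `substrate`, `state2`..`state3u`, `nonmito`, `rcr`, `clamped`.
#' @param rcr_method "per_well" or "of_means", see [ocr_states()].
#' @return data.frame per mouse x substrate with `n_wells`.
#' @export
aggregate_mouse <- function(per_well, rcr_method = c("per_well", "of_means")) {
  rcr_method <- match.arg(rcr_method)
  key <- interaction(per_well$mouse_id, per_well$substrate, drop = TRUE)
  out <- do.call(rbind, lapply(split(per_well, key), function(d) {
    data.frame(
      mouse_id = d$mouse_id[1], substrate = d$substrate[1],
      state2 = mean(d$state2), state3 = mean(d$state3),
      state4o = mean(d$state4o), state3u = mean(d$state3u),
      nonmito = mean(d$nonmito),
      rcr = if (rcr_method == "per_well") mean(d$rcr)
            else as.numeric(rcr(mean(d$state3), mean(d$state4o))),
      n_wells = nrow(d), any_clamped = any(d$clamped),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(out$mouse_id, out$substrate), , drop = FALSE]
}
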