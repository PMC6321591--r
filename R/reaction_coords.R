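# Reaction coordinates as signed linear combinations of named interatomic
# distances, the canonical reaction coordinate (accumulated path length),
# and projections of energy profiles onto chosen coordinates.
#
# Built-in definitions for the two phosphoryl-transfer steps of
# phosphoserine phosphatase:
#   OPO_step1 =  d(Ser-OG--P)  - d(P--OD-Asp11)    (P-O break/form, step 1)
#   OHO_step1 = -d(Ser-OG--H)  + d(H--OD-Asp13)    (proton transfer, step 1)
#   OPO_step2 =  d(P--OD-Asp11) - d(wat-O--P)      (P-O break/form, step 2)
#   OHO_step2 =  d(wat-O--H)   - d(H--OT-Asp11)    (proton transfer, step 2)
#   OHO_step2_asp13 = d(wat-O--H) - d(H--OD-Asp13) (step-2 proton-transfer
#                                                   variant used with the 2D
#                                                   free-energy analyses)
# Both step-2 proton-transfer variants ship because both appear in practice;
# neither is privileged.

# Registry of label variants -> canonical keys.  Distance labels in the
# literature vary between hyphenated and compact spellings; everything is
# normalised before matching.
.canonical_labels <- c(
  "serogp"   = "ser_og_p",  "serog_p"  = "ser_og_p",
  "podasp11" = "p_od_asp11", "poasp11"  = "p_od_asp11",
  "hodasp13" = "h_od_asp13",
  "serogh"   = "ser_og_h",
  "seroth"   = "ser_ot_h",
  "watop"    = "wat_o_p",  "watopp"   = "wat_o_p",
  "watoh"    = "wat_o_h",
  "hotasp11" = "h_ot_asp11"
)

#' Canonicalise an interatomic-distance label
#'
#' Distance labels appear in several spellings ("P-OD-Asp11" vs "P-O-Asp11",
#' "watO-P" vs "Wat-O-P", arbitrary dash characters).  This helper lowercases
#' a label, strips a leading `d(`/trailing `)`, removes all separators, and
#' maps known variants to a canonical snake_case key; unknown labels are
#' returned as their normalised form.
#'
#' @param label character vector of labels.
#' @return Character vector of canonical keys.
#' @examples
#' canonical_distance_label(c("d(SerOG-P)", "P-O-Asp11", "Wat-O--P"))
#' @export
canonical_distance_label <- function(label) {
  x <- tolower(label)
  x <- gsub("^d\\(", "", x)
  x <- gsub("\\)$", "", x)
  x <- gsub("[^a-z0-9]+", "", x)
  hit <- .canonical_labels[x]
  miss <- is.na(hit)
  # unknown labels: normalised snake_case-ish form
  hit[miss] <- gsub("[^a-z0-9]+", "_", tolower(label[miss]))
  unname(hit)
}

#' Define a reaction coordinate as a signed sum of distances
#'
#' @param name coordinate name.
#' @param terms named numeric vector of signs (+1 / -1), names being
#'   distance labels (canonicalised via [canonical_distance_label()]).
#' @return An `rc_definition`.
#' @examples
#' rc_definition("OPO_step1", c("Ser-OG-P" = 1, "P-OD-Asp11" = -1))
#' @export
rc_definition <- function(name, terms) {
  stopifnot(length(terms) >= 1, all(terms %in% c(-1, 1)),
            !is.null(names(terms)))
  labels <- canonical_distance_label(names(terms))
  if (anyDuplicated(labels))
    stop("duplicate distance label in reaction-coordinate definition")
  names(terms) <- labels
  structure(list(name = name, terms = terms), class = "rc_definition")
}

#' @export
print.rc_definition <- function(x, ...) {
  s <- paste(ifelse(x$terms > 0, "+", "-"), "d(", names(x$terms), ")",
             sep = "", collapse = " ")
  cat(x$name, "=", s, "\n")
  invisible(x)
}

#' Built-in reaction-coordinate definitions
#'
#' The phosphoryl-transfer (`OPO_*`, breaking/forming P-O bonds) and
#' proton-transfer (`OHO_*`, donor/acceptor O-H distances) coordinates of
#' the two catalytic steps of phosphoserine phosphatase.  Two step-2
#' proton-transfer variants exist (acceptor `OT-Asp11` vs `OD-Asp13`); both
#' are provided.
#'
#' @param name optional single definition to return; omit for the full list.
#' @return An `rc_definition`, or a named list of all of them.
#' @export
rc_builtins <- function(name = NULL) {
  defs <- list(
    OPO_step1 = rc_definition("OPO_step1",
      c(ser_og_p = 1, p_od_asp11 = -1)),
    OHO_step1 = rc_definition("OHO_step1",
      c(ser_og_h = -1, h_od_asp13 = 1)),
    OPO_step2 = rc_definition("OPO_step2",
      c(p_od_asp11 = 1, wat_o_p = -1)),
    OHO_step2 = rc_definition("OHO_step2",
      c(wat_o_h = 1, h_ot_asp11 = -1)),
    OHO_step2_asp13 = rc_definition("OHO_step2_asp13",
      c(wat_o_h = 1, h_od_asp13 = -1))
  )
  if (is.null(name)) return(defs)
  if (!name %in% names(defs)) stop("unknown built-in definition: ", name)
  defs[[name]]
}

#' Evaluate a reaction coordinate on distance frames
#'
#' Computes the signed sum of distances for each frame.  All distances are
#' in A; a missing distance label raises an error naming it.
#'
#' @param defn an `rc_definition`.
#' @param frame named numeric vector of distances, or a data frame with one
#'   column per distance label (column names canonicalised) and one row per
#'   frame.
#' @return Numeric vector of reaction-coordinate values, A.
#' @examples
#' eval_rc(rc_builtins("OPO_step1"),
#'         c(`Ser-OG-P` = 2.04, `P-O-Asp11` = 2.94))  # -0.90
#' @export
eval_rc <- function(defn, frame) {
  stopifnot(inherits(defn, "rc_definition"))
  if (is.data.frame(frame)) {
    cols <- canonical_distance_label(names(frame))
    miss <- setdiff(names(defn$terms), cols)
    if (length(miss) > 0)
      stop("distance label(s) missing from frame: ",
           paste(miss, collapse = ", "))
    v <- numeric(nrow(frame))
    for (lab in names(defn$terms))
      v <- v + defn$terms[[lab]] * frame[[which(cols == lab)[1]]]
    return(v)
  }
  labs <- canonical_distance_label(names(frame))
  miss <- setdiff(names(defn$terms), labs)
  if (length(miss) > 0)
    stop("distance label(s) missing from frame: ",
         paste(miss, collapse = ", "))
  sum(defn$terms * as.numeric(frame)[match(names(defn$terms), labs)])
}

#' Canonical reaction coordinate: accumulated path length
#'
#' @param path a `chain_path`, `grid_path`, or a matrix of path points.
#' @param normalize rescale to `[0, 1]`?
#' @return Strictly increasing numeric vector starting at 0 (A, or unitless
#'   if normalised).
#' @export
canonical_rc <- function(path, normalize = FALSE) {
  X <- if (inherits(path, "chain_path")) path$points
       else if (inherits(path, "grid_path")) as.matrix(path[, c("x", "y")])
       else rbind(path)
  seg <- sqrt(rowSums((X[-1, , drop = FALSE] -
                         X[-nrow(X), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (normalize) s <- s / s[length(s)]
  s
}

#' Project a path energy profile onto reaction coordinates
#'
#' Re-labels the abscissa of an energy profile by the value of one or two
#' reaction coordinates evaluated on per-point distance frames.  The points
#' stay in PATH order -- a non-monotone projection is preserved (not
#' re-sorted), so that corner cutting along the path remains visible; the
#' attached monotonicity report states whether the projection is injective.
#'
#' @param energies per-point energies along the path, kcal/mol.
#' @param frames data frame of distances, one row per path point.
#' @param defns an `rc_definition` or list of 1-2 of them.
#' @return Data frame with the projected coordinate column(s) and `energy`,
#'   in path order, with attribute `monotonicity` = list(injective,
#'   increasing, decreasing) for the first coordinate.
#' @export
project_profile <- function(energies, frames, defns) {
  if (inherits(defns, "rc_definition")) defns <- list(defns)
  stopifnot(length(defns) %in% 1:2)
  if (nrow(frames) != length(energies))
    stop("frames and energies differ in length (", nrow(frames), " vs ",
         length(energies), ")")
  out <- data.frame(row.names = seq_along(energies))
  for (d in defns) out[[d$name]] <- eval_rc(d, frames)
  out$energy <- energies
  r1 <- out[[1]]
  inc <- all(diff(r1) > 0); dec <- all(diff(r1) < 0)
  structure(out,
            monotonicity = list(injective = inc || dec,
                                increasing = inc, decreasing = dec))
}

#' Bundled stationary-state distance frames for the PSP phosphoryl transfer
#'
#' Interatomic distances (A) at the intermediate (IM), transition (TS) and
#' product (P) states of the two phosphoryl-transfer steps of phosphoserine
#' phosphatase, as characterised by minimum-energy-path, constrained-scan
#' and umbrella-sampling analyses, together with the tabulated
#' reaction-coordinate values (`rc1`, `rc2`).  Umbrella-sampling rows are
#' window means.  Used to verify the reaction-coordinate arithmetic.
#'
#' @return Data frame with columns `step`, `method`, `state`, `rc1`, `rc2`
#'   and canonical distance columns (NA where a distance does not apply to
#'   a step).
#' @export
psp_reference_frames <- function() {
  path <- system.file("extdata", "psp_state_distances.tsv",
                      package = "pmfpath", mustWork = TRUE)
  read_distance_frames(path)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Tabulated reaction-coordinate values are printed at one decimal with
#' conventional (half-up) rounding; base R's `round()` rounds half to even,
#' so comparisons against printed values use this helper.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
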