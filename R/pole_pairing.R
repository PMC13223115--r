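# Pairing spindle-pole annotations with segmented nuclei.

#' Match spindle-pole midpoints to nucleus centroids
#'
#' Greedy one-to-one nearest-neighbour matching: candidate pairs within
#' `max_dist_um` are taken in ascending distance order, each pole and nucleus
#' matched at most once. Distance ties below 1e-9 um are broken by
#' lexicographic (pole id, nucleus id) order, which makes the result
#' invariant to input ordering. Everything is reported: matches, unmatched
#' poles (nearest nucleus beyond the cap or already taken), and for each
#' match whether a second nucleus lay within the cap (ambiguous).
#'
#' @param pole_midpoints `n x 3` matrix of pole-pair midpoints; rownames used
#'   as ids (default `P1..Pn`).
#' @param nucleus_centroids `m x 3` matrix; rownames used as ids.
#' @param max_dist_um matching distance cap (micrometres, > 0; default 10).
#' @return a `pairing_result`: list with `matches` (data.frame `pole_id`,
#'   `nucleus_id`, `distance_um`, `ambiguous`), `unmatched_poles` (character).
#' @export
match_poles_to_nuclei <- function(pole_midpoints, nucleus_centroids,
                                  max_dist_um = 10) {
  if (max_dist_um <= 0) stop_mdp("mdp_parameter_error", "max_dist must be > 0")
  P <- rbind(pole_midpoints); N <- rbind(nucleus_centroids)
  pid <- if (!is.null(rownames(P))) rownames(P) else sprintf("P%d", seq_len(nrow(P)))
  nid <- if (!is.null(rownames(N))) rownames(N) else sprintf("N%d", seq_len(nrow(N)))
  # all candidate pairs within the cap
  cand <- do.call(rbind, lapply(seq_len(nrow(P)), function(i) {
    d <- sqrt((N[, 1] - P[i, 1])^2 + (N[, 2] - P[i, 2])^2 +
              (N[, 3] - P[i, 3])^2)
    j <- which(d <= max_dist_um)
    if (!length(j)) return(NULL)
    data.frame(pole = i, nucleus = j, d = d[j])
  }))
  matches <- data.frame(pole_id = character(0), nucleus_id = character(0),
                        distance_um = numeric(0), ambiguous = logical(0),
                        stringsAsFactors = FALSE)
  pole_taken <- rep(FALSE, nrow(P)); nuc_taken <- rep(FALSE, nrow(N))
  if (!is.null(cand) && nrow(cand)) {
    n_cand_per_pole <- table(factor(cand$pole, levels = seq_len(nrow(P))))
    # ascending distance, ties broken lexicographically by ids
    cand <- cand[order(round(cand$d / 1e-9) * 1e-9, pid[cand$pole],
                       nid[cand$nucleus]), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand$pole[r]; j <- cand$nucleus[r]
      if (pole_taken[i] || nuc_taken[j]) next
      pole_taken[i] <- TRUE; nuc_taken[j] <- TRUE
      matches <- rbind(matches, data.frame(
        pole_id = pid[i], nucleus_id = nid[j], distance_um = cand$d[r],
        ambiguous = n_cand_per_pole[i] > 1, stringsAsFactors = FALSE))
    }
  }
  structure(list(matches = matches,
                 unmatched_poles = pid[!pole_taken]),
            class = "pairing_result")
}

#' @export
print.pairing_result <- function(x, ...) {
  cat(sprintf("pairing_result: %d matched, %d unmatched poles (%d ambiguous)\n",
              nrow(x$matches), length(x$unmatched_poles),
              sum(x$matches$ambiguous)))
  invisible(x)
}
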