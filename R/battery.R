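#' Default pitch-test battery design
#'
#' A parameter grid of (f0, n_min, N) cells. Each cell defines one sound pair:
#' the first member is the grid sound itself, the second raises n_min by one
#' and lowers F0 so that the highest sounding harmonic keeps exactly the same
#' frequency while F0 and the spectral pitch F_SP move in opposite directions.
#' The default grid (9 log-spaced F0 values x n_min 2..7 x N 2..4) yields the
#' canonical battery size of 162 pairs / 324 unique sounds. The grid itself is
#' configurable; the pairing constraints, not the particular grid, carry the
#' design.
#'
#' @param f0_hz base fundamental frequencies (Hz).
#' @param n_min lowest sounding harmonic orders (integers >= 2).
#' @param n_harmonics harmonic counts N.
#' @return data.frame with one row per cell.
#' @export
default_battery_design <- function(f0_hz = exp(seq(log(100), log(400),
                                                   length.out = 9)),
                                   n_min = 2:7, n_harmonics = 2:4) {
  g <- expand.grid(f0_hz = f0_hz, n_min = n_min, n_harmonics = n_harmonics,
                   KEEP.OUT.ATTRS = FALSE)
  g[order(g$n_min, g$n_harmonics, g$f0_hz), , drop = FALSE]
}

# Construct the opposing-member spec for a design cell: n_min + 1 harmonics
# at a lower F0 chosen so the top harmonic frequency is preserved.
opposing_member <- function(f0_hz, n_min, n_harmonics) {
  m <- n_min + n_harmonics - 1L            # top order of the first member
  list(f0_hz = f0_hz * m / (m + 1L), n_min = n_min + 1L,
       n_harmonics = n_harmonics)
}

#' Build the paired missing-fundamental test battery
#'
#' For every design cell, two harmonic complexes are paired such that the
#' periodicity frequency F0 changes in the opposite direction of the spectral
#' frequency F_SP while the frequency of the highest sounding harmonic is
#' identical across the two members (suppressing edge-pitch cues). The pair
#' order and the within-pair sound order (hence the relative pitch direction)
#' are pseudo-randomized by \code{order_seed} and identical for every run with
#' the same seed.
#'
#' @param design design grid as from \code{\link{default_battery_design}}.
#' @param order_seed integer seed fixing pair order and within-pair order.
#' @param isi_s inter-stimulus interval within a pair (s).
#' @return an object of class \code{test_battery}: list with \code{pairs} (a
#'   list of \code{sound_pair}), \code{order_seed}, \code{isi_s}.
#' @export
build_battery <- function(design = default_battery_design(), order_seed = 1L,
                          isi_s = 0.4) {
  stopifnot(nrow(design) >= 1)
  pairs <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    a <- harmonic_complex(design$f0_hz[i], design$n_min[i],
                          design$n_harmonics[i])
    ob <- opposing_member(design$f0_hz[i], design$n_min[i],
                          design$n_harmonics[i])
    b <- harmonic_complex(ob$f0_hz, ob$n_min, ob$n_harmonics)
    pairs[[i]] <- sound_pair(a, b, pair_id = sprintf("pair%03d", i))
  }
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(as.integer(order_seed))
    ord <- sample.int(length(pairs))
    flip <- sample(c(TRUE, FALSE), length(pairs), replace = TRUE)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    list(ord = ord, flip = flip)
  })
  pairs <- pairs[rng$ord]
  for (i in seq_along(pairs)) {
    if (rng$flip[i]) {
      p <- pairs[[i]]
      pairs[[i]] <- sound_pair(p$second, p$first, pair_id = p$pair_id)
    }
  }
  structure(list(pairs = pairs, order_seed = as.integer(order_seed),
                 isi_s = isi_s),
            class = "test_battery")
}

#' Construct a sound pair with opposing pitch cues
#'
#' Validates that F0 and F_SP move in opposite (nonzero) directions between
#' the members and that the highest sounding harmonic frequency matches.
#'
#' @param first,second \code{harmonic_complex} members in presentation order.
#' @param pair_id unique label.
#' @return an object of class \code{sound_pair}.
#' @export
sound_pair <- function(first, second, pair_id) {
  d_f0 <- second$f0_hz - first$f0_hz
  d_fsp <- spectral_pitch(second) - spectral_pitch(first)
  if (d_f0 == 0 || d_fsp == 0)
    stop(sprintf("pair %s: F0 or F_SP does not change between members", pair_id))
  if (sign(d_f0) == sign(d_fsp))
    stop(sprintf("pair %s: F0 and F_SP must move in opposite directions", pair_id))
  top1 <- first$f0_hz * (first$n_min + first$n_harmonics - 1L)
  top2 <- second$f0_hz * (second$n_min + second$n_harmonics - 1L)
  if (abs(top1 - top2) / top1 > 1e-9)
    stop(sprintf("pair %s: highest harmonic differs (%.6f vs %.6f Hz)",
                 pair_id, top1, top2))
  structure(list(first = first, second = second, pair_id = pair_id,
                 d_f0 = d_f0, d_fsp = d_fsp),
            class = "sound_pair")
}

#' @export
print.test_battery <- function(x, ...) {
  cat(sprintf("<test_battery> %d pairs (%d unique sounds), order_seed = %d, ISI = %.2f s\n",
              length(x$pairs), nrow(battery_manifest(x)) * 2L -
                sum(duplicated(c(vapply(x$pairs, function(p) p$first$id, ""),
                                 vapply(x$pairs, function(p) p$second$id, "")))),
              x$order_seed, x$isi_s))
  invisible(x)
}

#' Battery manifest table
#'
#' One row per pair in presentation order, recording both members' parameters
#' and the direction of the F0 and F_SP changes from first to second sound.
#'
#' @param battery a \code{test_battery}.
#' @return data.frame.
#' @export
battery_manifest <- function(battery) {
  rows <- lapply(battery$pairs, function(p) {
    data.frame(pair_id = p$pair_id,
               first_id = p$first$id, second_id = p$second$id,
               f0_first = p$first$f0_hz, f0_second = p$second$f0_hz,
               n_min_first = p$first$n_min, n_min_second = p$second$n_min,
               n_harm_first = p$first$n_harmonics,
               n_harm_second = p$second$n_harmonics,
               fsp_first = spectral_pitch(p$first),
               fsp_second = spectral_pitch(p$second),
               f0_direction = sign(p$d_f0), fsp_direction = sign(p$d_fsp))
  })
  do.call(rbind, rows)
}

#' Classify a two-alternative pitch response
#'
#' A listener reports which tone of a pair sounded higher. If the reported
#' direction matches the F0 change the response is consistent with
#' fundamental (periodicity) pitch perception; if it matches the F_SP change
#' it is consistent with spectral pitch perception. By the opposing-cue
#' construction exactly one of the two matches.
#'
#' @param pair a \code{sound_pair}.
#' @param answer \code{"first_higher"} or \code{"second_higher"}.
#' @return \code{"fundamental"} or \code{"spectral"}.
#' @export
classify_response <- function(pair, answer = c("first_higher", "second_higher")) {
  answer <- match.arg(answer)
  if (pair$d_f0 == 0 || pair$d_fsp == 0)
    stop("unclassifiable stimulus: F0 or F_SP identical within the pair")
  reported <- if (answer == "second_higher") 1 else -1
  if (reported == sign(pair$d_f0)) "fundamental" else "spectral"
}

#' Tally classified pitch responses
#'
#' @param responses character vector of \code{"spectral"} /
#'   \code{"fundamental"} classifications.
#' @return list with counts \code{n_sp} and \code{n_f0}.
#' @export
response_tally <- function(responses) {
  stopifnot(all(responses %in% c("spectral", "fundamental")))
  list(n_sp = sum(responses == "spectral"),
       n_f0 = sum(responses == "fundamental"))
}

#' Pitch perception index
#'
#' delta_P = (n_SP - n_F0) / (n_SP + n_F0), ranging from -1 (every classified
#' response consistent with the missing fundamental; an extreme fundamental
#' pitch perceiver) to +1 (every response consistent with the spectral
#' envelope; an extreme spectral pitch perceiver). 0 corresponds to 50/50
#' odds.
#'
#' @param n_sp count of spectral-consistent responses (or a tally list from
#'   \code{\link{response_tally}}).
#' @param n_f0 count of fundamental-consistent responses.
#' @return list with \code{delta_p} and \code{n_classified}.
#' @export
pitch_index <- function(n_sp, n_f0) {
  if (is.list(n_sp) && missing(n_f0)) {
    n_f0 <- n_sp$n_f0
    n_sp <- n_sp$n_sp
  }
  stopifnot(n_sp >= 0, n_f0 >= 0)
  total <- n_sp + n_f0
  if (total == 0) stop("no classified responses: pitch index undefined")
  list(delta_p = (n_sp - n_f0) / total, n_classified = as.integer(total))
}

#' Score a response log against a battery
#'
#' @param battery a \code{test_battery}.
#' @param answers character vector (one per pair, in battery order) of
#'   \code{"first_higher"} / \code{"second_higher"}.
#' @return a pitch-index result list (see \code{\link{pitch_index}}).
#' @export
score_battery <- function(battery, answers) {
  stopifnot(length(answers) == length(battery$pairs))
  cls <- mapply(function(p, a) classify_response(p, a), battery$pairs, answers)
  pitch_index(response_tally(cls))
}
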