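#' Trial timeline landmarks
#'
#' Constructs the within-trial timeline of the preferential-looking task.
#' A trial lasts 8,000 ms: a central fixation point from 0 to 1,000 ms, the
#' two competitor pictures from 1,000 to 7,000 ms, and a blank final second.
#' The carrier sentence places the verb 2,000 ms and the direct-object noun
#' 4,000 ms after picture onset.  All analysis windows use *relative* time,
#' with 0 = picture onset, so the pictures are on screen for relative
#' 0--6,000 ms.
#'
#' @param fixation_onset_abs Fixation-point onset, absolute ms.
#' @param picture_onset_abs Picture onset, absolute ms; the origin of
#'   relative time.
#' @param verb_onset_rel Verb onset, ms relative to picture onset.
#' @param noun_onset_rel Noun onset, ms relative to picture onset.
#' @param picture_offset_rel Picture offset, ms relative to picture onset.
#' @param trial_end_abs Trial end, absolute ms.
#' @return An object of class `"pl_timeline"`: a named list of the six
#'   landmarks.
#' @examples
#' tl <- pl_timeline()
#' tl$noun_onset_rel  # 4000
#' @export
pl_timeline <- function(fixation_onset_abs = 0, picture_onset_abs = 1000,
                        verb_onset_rel = 2000, noun_onset_rel = 4000,
                        picture_offset_rel = 6000, trial_end_abs = 8000) {
  if (!(fixation_onset_abs >= 0 && fixation_onset_abs < picture_onset_abs))
    stop("fixation onset must lie in [0, picture onset)")
  if (!(verb_onset_rel < noun_onset_rel && noun_onset_rel < picture_offset_rel))
    stop("timeline must order verb < noun < picture offset")
  if (trial_end_abs < picture_onset_abs + picture_offset_rel)
    stop("trial must not end before picture offset")
  structure(list(fixation_onset_abs = fixation_onset_abs,
                 picture_onset_abs = picture_onset_abs,
                 verb_onset_rel = verb_onset_rel,
                 noun_onset_rel = noun_onset_rel,
                 picture_offset_rel = picture_offset_rel,
                 trial_end_abs = trial_end_abs),
            class = "pl_timeline")
}

#' Screen geometry
#'
#' @param width_px,height_px Screen size in pixels; both must be positive.
#'   The reference display is 1920 x 1080.
#' @return An object of class `"pl_screen"`.
#' @examples
#' pl_screen(1600, 1200)
#' @export
pl_screen <- function(width_px = 1920, height_px = 1080) {
  if (!(width_px > 0 && height_px > 0)) stop("screen dimensions must be positive")
  structure(list(width_px = width_px, height_px = height_px), class = "pl_screen")
}

#' Rectangular area of interest
#'
#' An AOI is stored by its *center* and size.  On the reference 1920 x 1080
#' display each picture's AOI is one 960 x 1080 screen half, so the left AOI
#' center sits at (480, 540).
#'
#' @param center_x,center_y Box center in pixels.
#' @param width,height Box size in pixels.
#' @param side `"left"` or `"right"`.
#' @return An object of class `"pl_aoi"`.
#' @examples
#' pl_aoi(480, 540, 960, 1080, "left")
#' @export
pl_aoi <- function(center_x, center_y, width, height, side = c("left", "right")) {
  side <- match.arg(side)
  if (!(width > 0 && height > 0)) stop("AOI dimensions must be positive")
  structure(list(center_x = center_x, center_y = center_y,
                 width = width, height = height, side = side),
            class = "pl_aoi")
}

#' Default left/right AOIs for a reference screen
#'
#' Splits the screen into two half-screen AOIs (each width/2 x height).
#'
#' @param screen A [pl_screen()].
#' @return A list with elements `left` and `right`, each a [pl_aoi()].
#' @export
pl_default_aois <- function(screen = pl_screen()) {
  w <- screen$width_px; h <- screen$height_px
  list(left  = pl_aoi(w / 4,     h / 2, w / 2, h, "left"),
       right = pl_aoi(3 * w / 4, h / 2, w / 2, h, "right"))
}

#' Rescale an AOI from a reference screen to a participant's screen
#'
#' Webcam studies run on heterogeneous displays, so AOIs defined on the
#' reference screen are rescaled in proportion to the actual screen size.
#' Width and center x are scaled by `actual_w / reference_w`, and height and
#' center y by `actual_h / reference_h`, independently.  A 960 x 1080 AOI
#' centred at (480, 540) on a 1920 x 1080 reference becomes an 800 x 1200 AOI
#' centred at (400, 600) on a 1600 x 1200 screen.
#'
#' @param box A [pl_aoi()] defined on `reference`.
#' @param reference,actual [pl_screen()] objects (or 2-vectors
#'   `c(width, height)`).
#' @return The rescaled [pl_aoi()].
#' @examples
#' b <- pl_aoi(480, 540, 960, 1080, "left")
#' scale_aoi(b, pl_screen(1920, 1080), pl_screen(1600, 1200))
#' @export
scale_aoi <- function(box, reference, actual) {
  reference <- as_screen(reference); actual <- as_screen(actual)
  sx <- actual$width_px / reference$width_px
  sy <- actual$height_px / reference$height_px
  pl_aoi(box$center_x * sx, box$center_y * sy,
         box$width * sx, box$height * sy, box$side)
}

as_screen <- function(x) {
  if (inherits(x, "pl_screen")) return(x)
  if (is.numeric(x) && length(x) == 2) return(pl_screen(x[1], x[2]))
  stop("expected a pl_screen or a numeric c(width, height)")
}

# Sentence inventory: 56 items.  Items 1-14 carry a closely related verb (CV),
# 15-28 a moderately related verb (MV).  Each predictive item p shares its
# image pair with an unrelated-verb (UV) recording of the same target noun:
# item p + 28.  The image-pair id is therefore p for items 1-28 and p - 28
# for items 29-56.
#' Sentence/item inventory
#'
#' @return A data.frame with one row per item: `item_id` (1--56), `condition`
#'   (CV/MV/UV) and `pair_id` (1--28), the shared target/distractor image
#'   pair.
#' @export
item_inventory <- function() {
  data.frame(
    item_id = 1:56,
    condition = rep(c("CV", "MV", "UV"), c(14, 14, 28)),
    pair_id = c(1:28, 1:28),
    stringsAsFactors = FALSE
  )
}

#' Build one participant's counterbalanced trial list
#'
#' Each participant hears 28 sentences -- 7 CV, 7 MV and 14 UV -- drawn from
#' the 56-item inventory so that each target/distractor image pair appears
#' exactly once per participant: for every pair the participant gets either
#' the predictive (CV or MV) or the unrelated (UV) version.  Four
#' counterbalancing orders rotate which half of each predictive set is heard
#' in its predictive form, and alternate ascending/descending presentation.
#' Target side is assigned by the seeded RNG, balanced 14 left / 14 right.
#'
#' @param participant_id Identifier copied into every row.
#' @param order_id Counterbalancing order, 1--4.
#' @param seed Integer seed controlling trial shuffling and side assignment.
#' @return A data.frame of 28 rows: `participant_id`, `trial_index`,
#'   `condition`, `item_id`, `pair_id`, `target_side`, `order_id`.
#' @examples
#' d <- build_design("p01", order_id = 1, seed = 7)
#' table(d$condition)  # CV 7, MV 7, UV 14
#' @export
build_design <- function(participant_id, order_id, seed = 1L) {
  if (!(length(order_id) == 1 && order_id %in% 1:4))
    stop("order_id must be one of 1, 2, 3, 4")
  inv <- item_inventory()
  # orders 1,3 hear predictive items for the first half of each pair block;
  # orders 2,4 hear the complementary half.
  first_half <- order_id %in% c(1, 3)
  cv_pred <- if (first_half) 1:7 else 8:14      # pair ids heard as CV
  mv_pred <- if (first_half) 15:21 else 22:28   # pair ids heard as MV
  pred_pairs <- c(cv_pred, mv_pred)
  items <- ifelse(1:28 %in% pred_pairs, 1:28, (1:28) + 28L)
  trials <- inv[match(items, inv$item_id), ]
  rng <- local_rng(seed + 17L * order_id)
  # ascending for orders 1-2, descending for 3-4, with a seeded interleave
  ord <- rng_sample(rng, nrow(trials))
  if (!(order_id %in% c(1, 2))) ord <- rev(ord)
  trials <- trials[ord, ]
  side <- rng_sample(rng, rep(c("left", "right"), each = 14))
  data.frame(
    participant_id = participant_id,
    trial_index = 1:28,
    condition = trials$condition,
    item_id = trials$item_id,
    pair_id = trials$pair_id,
    target_side = side,
    order_id = order_id,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# A tiny local RNG wrapper: evaluates expressions under a private seed
# without disturbing the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$seed <- as.integer(seed %% .Machine$integer.max)
  env
}

rng_sample <- function(rng, x, size = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(rng$seed)
  rng$seed <- rng$seed + 1L
  if (is.null(size)) sample(x) else sample(x, size)
}
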