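#' EORTC QLQ-C30 dimension table
#'
#' The 15 dimensions of the QLQ-C30 (version 3.0): global health status,
#' five functional scales and nine symptom scales/items, with their item
#' assignments and item ranges.
#'
#' @return A tibble with columns `dimension` (short code), `type`
#'   (`"global"`, `"functional"` or `"symptom"`), `items` (list of item
#'   numbers) and `range` (item range: 3 for 4-point items, 6 for the two
#'   7-point global items).
#' @examples
#' qlq_dimensions()
#' @export
qlq_dimensions <- function() {
  tibble(
    dimension = c(
      "ql", "pf", "rf", "ef", "cf", "sf",
      "fa", "nv", "pa", "dy", "sl", "ap", "co", "di", "fi"
    ),
    type = c("global", rep("functional", 5), rep("symptom", 9)),
    items = list(
      c(29L, 30L), 1:5, 6:7, 21:24, c(20L, 25L), 26:27,
      c(10L, 12L, 18L), 14:15, c(9L, 19L), 8L, 11L, 13L, 16L, 17L, 28L
    ),
    range = c(6L, rep(3L, 14))
  )
}

qlq_dimension_names <- function() qlq_dimensions()$dimension

#' Score QLQ-C30 item responses into dimension scores
#'
#' Applies the standard EORTC linear scoring transform. For each dimension
#' the raw score RS is the mean of its item responses; functional scales are
#' scored `(1 - (RS - 1) / range) * 100` (higher = better functioning),
#' symptom scales `((RS - 1) / range) * 100` (higher = worse symptoms), and
#' global health `((RS - 1) / 6) * 100`.
#'
#' @param items A data frame with item columns `q01`..`q30` (one row per
#'   respondent), or a single numeric vector of length 30. Items 1-28 take
#'   values in 1..4; the global items 29-30 take values in 1..7.
#'
#' @return A tibble with one row per respondent and one column per
#'   dimension (`ql`, `pf`, ..., `fi`), all scores in \[0, 100\].
#' @examples
#' # all items at their best level: functional scales 100, symptoms 0
#' best <- c(rep(1, 28), 7, 7)
#' score_qlq_items(best)
#' @export
score_qlq_items <- function(items) {
  if (is.numeric(items) && is.null(dim(items))) {
    if (length(items) != 30) {
      abort("`items` as a vector must have length 30.", class = "eprocua_validation_error")
    }
    items <- as_tibble(as.list(setNames(items, sprintf("q%02d", 1:30))))
  }
  items <- as_tibble(items)
  cols <- sprintf("q%02d", 1:30)
  missing_cols <- setdiff(cols, names(items))
  if (length(missing_cols)) {
    abort(
      paste0("Missing item columns: ", paste(missing_cols, collapse = ", ")),
      class = "eprocua_schema_error"
    )
  }
  m <- as.matrix(items[cols])
  hi <- c(rep(4, 28), 7, 7)
  bad <- which(!is.na(m) & (m < 1 | m > rep(hi, each = nrow(m))), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(
      sprintf(
        "Out-of-range item responses (first at row %d, item %s).",
        bad[1, 1], cols[bad[1, 2]]
      ),
      class = "eprocua_validation_error"
    )
  }
  dims <- qlq_dimensions()
  out <- purrr::pmap(dims, function(dimension, type, items, range) {
    rs <- rowMeans(m[, sprintf("q%02d", items), drop = FALSE])
    if (type == "functional") {
      (1 - (rs - 1) / range) * 100
    } else {
      ((rs - 1) / range) * 100
    }
  })
  as_tibble(setNames(out, dims$dimension))[qlq_dimension_names()]
}
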