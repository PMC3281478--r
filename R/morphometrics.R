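#' Length of a digitized landmark chain
#'
#' Segment lengths were digitized as ordered x,y coordinate points along the
#' segment; the length is the sum of Euclidean distances between consecutive
#' points, converted from pixels to millimetres by the image scale.
#'
#' @param points A two-column matrix or data frame of x,y coordinates in pixel
#'   units, ordered proximal to distal; at least two points.
#' @param scale_mm_per_px Millimetres per pixel (positive scalar). Default 1.
#' @return Length in mm (scalar).
#' @examples
#' polyline_length(rbind(c(0, 0), c(3, 4)))  # 5
#' @export
polyline_length <- function(points, scale_mm_per_px = 1) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2) {
    abort("`points` must be a two-column numeric matrix of x,y coordinates",
          class = "brushfoot_validation_error")
  }
  if (nrow(pts) < 2) {
    abort("degenerate chain: need at least 2 points",
          class = "brushfoot_validation_error")
  }
  if (!is.numeric(scale_mm_per_px) || length(scale_mm_per_px) != 1 ||
      !is.finite(scale_mm_per_px) || scale_mm_per_px <= 0) {
    abort("`scale_mm_per_px` must be a single positive number",
          class = "brushfoot_validation_error")
  }
  d <- diff(pts)
  sum(sqrt(rowSums(d^2))) * scale_mm_per_px
}

as_chain <- function(x, default_scale) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$points)) {
    list(points = x$points, scale = x$scale %||% default_scale)
  } else {
    list(points = x, scale = default_scale)
  }
}

#' Segment lengths of one limb from landmark chains
#'
#' The tarsus comprises five tarsomeres, digitized separately and analysed
#' combined: `tarsus_mm` is the sum of the five tarsomere chain lengths, and
#' `total_mm = femur_mm + tibia_mm + tarsus_mm`.
#'
#' @param femur,tibia Landmark chains: either a two-column coordinate matrix
#'   (using `scale_mm_per_px`) or a list `list(points = , scale = )` carrying
#'   its own mm-per-pixel scale.
#' @param tarsomeres A list of exactly 5 landmark chains, proximal tarsomere
#'   first.
#' @param scale_mm_per_px Default scale for chains that do not carry one.
#' @return A one-row tibble with `femur_mm`, `tibia_mm`, `tarsus_mm`,
#'   `total_mm`.
#' @export
limb_from_landmarks <- function(femur, tibia, tarsomeres, scale_mm_per_px = 1) {
  if (!is.list(tarsomeres) || length(tarsomeres) != 5) {
    abort(sprintf("expected 5 tarsomere chains, got %d",
                  if (is.list(tarsomeres)) length(tarsomeres) else 1L),
          class = "brushfoot_validation_error")
  }
  len <- function(x) {
    ch <- as_chain(x, scale_mm_per_px)
    polyline_length(ch$points, ch$scale)
  }
  femur_mm <- len(femur)
  tibia_mm <- len(tibia)
  tarsus_mm <- sum(vapply(tarsomeres, len, numeric(1)))
  tibble(femur_mm = femur_mm, tibia_mm = tibia_mm, tarsus_mm = tarsus_mm,
         total_mm = femur_mm + tibia_mm + tarsus_mm)
}

#' Relative T1 length
#'
#' The reduction statistic: the T1 value divided by the average of the T2 and
#' T3 values of the same trait. `r = 1` is the isometry baseline (T1 equal to
#' the mean of the walking limbs); nymphalid and riodinid forelimbs fall well
#' below it. The statistic is invariant under a common rescaling of all three
#' limbs, so absolute body size cancels.
#'
#' @param t1,t2,t3 Nonnegative lengths (vectorized).
#' @return `t1 / ((t2 + t3) / 2)`.
#' @examples
#' relative_t1_length(4, 5, 5)  # 0.8
#' @export
relative_t1_length <- function(t1, t2, t3) {
  if (any(c(t1, t2, t3) < 0, na.rm = TRUE)) {
    abort("lengths must be nonnegative", class = "brushfoot_validation_error")
  }
  denom <- (t2 + t3) / 2
  if (any(denom == 0, na.rm = TRUE)) {
    abort("undefined ratio: t2 and t3 are both zero",
          class = "brushfoot_validation_error")
  }
  t1 / denom
}

TRAIT_TABLE_COLS <- c("species", "sex", "limb", "femur_mm", "tibia_mm", "tarsus_mm")
TARSOMERE_COLS <- paste0("tarsomere_", 1:5, "_mm")

#' Coerce and validate a trait table
#'
#' A trait table holds one row per (species, sex, limb) with segment lengths
#' in mm. `total_mm` is always recomputed as femur + tibia + tarsus, never
#' trusted from input. If the five tarsomere columns are present and complete
#' for a row, they define `tarsus_mm`; a conflicting pre-combined `tarsus_mm`
#' (difference above 1e-9) is an error.
#'
#' @param df A data frame with columns `species`, `sex` (`"female"`/`"male"`),
#'   `limb` (`"T1"`/`"T2"`/`"T3"`), `femur_mm`, `tibia_mm`, `tarsus_mm`
#'   (optional when `tarsomere_1_mm`..`tarsomere_5_mm` are supplied).
#' @return A tibble with the canonical columns plus `total_mm`.
#' @export
as_trait_table <- function(df) {
  df <- as_tibble(df)
  has_tarsomeres <- all(TARSOMERE_COLS %in% names(df))
  required <- TRAIT_TABLE_COLS
  if (has_tarsomeres) required <- setdiff(required, "tarsus_mm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(paste0("trait table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "brushfoot_validation_error")
  }
  bad_sex <- setdiff(unique(df$sex), SEXES)
  if (length(bad_sex)) {
    abort(paste0("invalid sex value(s): ", paste(bad_sex, collapse = ", "),
                 " (expected ", paste(SEXES, collapse = "/"), ")"),
          class = "brushfoot_validation_error")
  }
  bad_limb <- setdiff(unique(df$limb), LIMBS)
  if (length(bad_limb)) {
    abort(paste0("invalid limb value(s): ", paste(bad_limb, collapse = ", "),
                 " (expected ", paste(LIMBS, collapse = "/"), ")"),
          class = "brushfoot_validation_error")
  }
  if (has_tarsomeres) {
    tarso_sum <- rowSums(df[TARSOMERE_COLS])
    if ("tarsus_mm" %in% names(df)) {
      conflict <- which(!is.na(df$tarsus_mm) & !is.na(tarso_sum) &
                          abs(df$tarsus_mm - tarso_sum) > 1e-9)
      if (length(conflict)) {
        k <- conflict[1]
        abort(sprintf(
          "tarsus_mm disagrees with the tarsomere sum for (%s, %s, %s)",
          df$species[k], df$sex[k], df$limb[k]),
          class = "brushfoot_validation_error")
      }
      df$tarsus_mm <- ifelse(is.na(tarso_sum), df$tarsus_mm, tarso_sum)
    } else {
      df$tarsus_mm <- tarso_sum
    }
  }
  key <- paste(df$species, df$sex, df$limb, sep = "|")
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (species, sex, limb) row(s): ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")),
          class = "brushfoot_validation_error")
  }
  for (col in c("femur_mm", "tibia_mm", "tarsus_mm")) {
    neg <- which(df[[col]] < 0)
    if (length(neg)) {
      k <- neg[1]
      abort(sprintf("negative %s for (%s, %s, %s)",
                    col, df$species[k], df$sex[k], df$limb[k]),
            class = "brushfoot_validation_error")
    }
  }
  df$total_mm <- df$femur_mm + df$tibia_mm + df$tarsus_mm
  select(df, all_of(c(TRAIT_TABLE_COLS, "total_mm")),
         any_of(TARSOMERE_COLS))
}

#' Read / write a trait table CSV
#'
#' Comma-separated, UTF-8, `.` decimal separator, header required. The
#' `total_mm` column is recomputed on read and never written; the round trip
#' `read_trait_table(write_trait_table(x, p))` is stable.
#'
#' @param path CSV file path.
#' @return `read_trait_table()`: a validated trait table tibble (see
#'   [as_trait_table()]). `write_trait_table()`: `path`, invisibly.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("trait table file not found: %s", path),
          class = "brushfoot_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_guess()),
                        progress = FALSE, show_col_types = FALSE)
  as_trait_table(df)
}

#' @rdname read_trait_table
#' @param table A trait table (validated with [as_trait_table()] first).
#' @export
write_trait_table <- function(table, path) {
  table <- as_trait_table(table)
  out <- select(table, all_of(TRAIT_TABLE_COLS), any_of(TARSOMERE_COLS))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a landmark table and convert it to a trait table
#'
#' The landmark CSV has one row per digitized point: columns `species`, `sex`,
#' `limb`, `segment` (`femur`, `tibia`, `tarsus`, or `tarsomere_1` ..
#' `tarsomere_5`), `point_index`, `x_px`, `y_px`, `scale_mm_per_px`. Points
#' are ordered by `point_index` within each chain; tarsomere chains are
#' summed into the combined tarsus.
#'
#' @param path Landmark CSV path.
#' @return A validated trait table tibble.
#' @export
traits_from_landmarks <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("landmark file not found: %s", path),
          class = "brushfoot_io_error")
  }
  lm <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("species", "sex", "limb", "segment", "point_index",
              "x_px", "y_px", "scale_mm_per_px")
  missing_cols <- setdiff(needed, names(lm))
  if (length(missing_cols)) {
    abort(paste0("landmark table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "brushfoot_validation_error")
  }
  seg_len <- lm |>
    arrange(.data$species, .data$sex, .data$limb, .data$segment,
            .data$point_index) |>
    group_by(.data$species, .data$sex, .data$limb, .data$segment) |>
    summarise(
      length_mm = polyline_length(cbind(.data$x_px, .data$y_px),
                                  .data$scale_mm_per_px[1]),
      .groups = "drop"
    ) |>
    mutate(segment = ifelse(grepl("^tarsomere_", .data$segment),
                            "tarsus", .data$segment)) |>
    group_by(.data$species, .data$sex, .data$limb, .data$segment) |>
    summarise(length_mm = sum(.data$length_mm), .groups = "drop")
  wide <- seg_len |>
    pivot_wider(names_from = "segment", values_from = "length_mm",
                names_glue = "{segment}_mm")
  as_trait_table(wide)
}
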