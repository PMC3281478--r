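#' Classify a relative T1 length against the reduction threshold
#'
#' A node's T1 trait is reduced iff `r < threshold` (strict): a node exactly
#' at the boundary — T1 at 80% of the T2/T3 average under the default — is
#' *not* reduced. The threshold is deliberately a parameter, not a constant:
#' 80% is a conservative but arbitrary convention.
#'
#' @param r Relative T1 length(s), nonnegative (see [relative_t1_length()]).
#' @param threshold Reduction threshold, typically in (0, 1). Default 0.8.
#' @return Logical vector: `TRUE` where reduced.
#' @examples
#' classify_reduced(c(0.79, 0.80, 1.2))  # TRUE FALSE FALSE
#' @export
classify_reduced <- function(r, threshold = 0.8) {
  if (any(r < 0, na.rm = TRUE)) {
    abort("relative length r must be nonnegative",
          class = "brushfoot_validation_error")
  }
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort("`threshold` must be a single positive number",
          class = "brushfoot_validation_error")
  }
  r < threshold
}

#' Relative T1 length and reduction status at every node
#'
#' For every node (observed tips, reconstructed ancestors) and every trait,
#' computes `r = T1 / mean(T2, T3)` from the node's three limb values and
#' classifies it against the threshold.
#'
#' @param ancestors Ancestral-state table from [reconstruct_all()] (contains
#'   both tip and internal values for all three limbs).
#' @param threshold Reduction threshold passed to [classify_reduced()].
#' @return A tibble: `node_id`, `label`, `type`, `sex`, `trait`, `t1_mm`,
#'   `t2_mm`, `t3_mm`, `r`, `reduced`.
#' @export
node_relative_lengths <- function(ancestors, threshold = 0.8) {
  needed <- c("node_id", "label", "type", "sex", "limb", "trait", "value_mm")
  missing_cols <- setdiff(needed, names(ancestors))
  if (length(missing_cols)) {
    abort(paste0("ancestral table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "brushfoot_validation_error")
  }
  wide <- ancestors |>
    pivot_wider(id_cols = c("node_id", "label", "type", "sex", "trait"),
                names_from = "limb", values_from = "value_mm")
  for (lb in LIMBS) {
    if (!lb %in% names(wide)) wide[[lb]] <- NA_real_
    bad <- which(is.na(wide[[lb]]))
    if (length(bad)) {
      k <- bad[1]
      abort(sprintf("missing %s value at node %d for %s %s",
                    lb, wide$node_id[k], wide$sex[k], wide$trait[k]),
            class = "brushfoot_validation_error")
    }
  }
  wide |>
    mutate(
      r = relative_t1_length(.data$T1, .data$T2, .data$T3),
      reduced = classify_reduced(.data$r, threshold)
    ) |>
    rename(t1_mm = "T1", t2_mm = "T2", t3_mm = "T3") |>
    arrange(.data$sex, .data$trait, .data$node_id)
}

#' Detect branches on which T1 reduction evolved
#'
#' A reduction event is a directed tree edge whose parent is not reduced
#' (`r >= threshold`) and whose child is reduced (`r < threshold`), evaluated
#' per trait and per sex independently. The root, having no ancestor, is
#' never the child of an event. Events are ordered by the child's preorder
#' position for determinism.
#'
#' @param statuses Node status table from [node_relative_lengths()].
#' @param tree The `phylo` object the statuses refer to.
#' @return A tibble: `sex`, `trait`, `parent_id`, `child_id`, `r_parent`,
#'   `r_child`, `child_label` (tip label or `NA`), `clade` (comma-joined tip
#'   labels subtended by the child).
#' @export
detect_reduction_events <- function(statuses, tree) {
  check_phylo(tree)
  m <- n_nodes(tree)
  edges <- preorder_edges(tree)
  pre_pos <- match(seq_len(m), preorder_nodes(tree))
  out <- statuses |>
    group_by(.data$sex, .data$trait) |>
    group_modify(function(df, key) {
      r <- rep(NA_real_, m)
      r[df$node_id] <- df$r
      red <- rep(NA, m)
      red[df$node_id] <- df$reduced
      ends <- unique(as.vector(edges))
      if (anyNA(red[ends])) {
        abort(sprintf("status missing for node(s) %s (%s, %s)",
                      paste(ends[is.na(red[ends])], collapse = ", "),
                      key$sex, key$trait),
              class = "brushfoot_validation_error")
      }
      hit <- !red[edges[, 1]] & red[edges[, 2]]
      ev <- edges[hit, , drop = FALSE]
      tibble(
        parent_id = ev[, 1],
        child_id = ev[, 2],
        r_parent = r[ev[, 1]],
        r_child = r[ev[, 2]]
      ) |> arrange(pre_pos[.data$child_id])
    }) |>
    ungroup()
  out |>
    mutate(
      child_label = ifelse(.data$child_id <= ape::Ntip(tree),
                           tree$tip.label[pmin(.data$child_id, ape::Ntip(tree))],
                           NA_character_),
      clade = vapply(.data$child_id, function(id) {
        paste(clade_tip_labels(tree, id), collapse = ",")
      }, character(1))
    )
}

#' Branches where both sexes show the same reduction event
#'
#' Convenience summary flagging sex-consistent events: branches on which the
#' same trait crosses the threshold in both the male and the female analysis
#' (the strongest, sex-independent signal of a reduction origin).
#'
#' @param events Event table from [detect_reduction_events()].
#' @return A tibble `trait`, `parent_id`, `child_id`, `clade`, `n_sexes`,
#'   `sexes`, filtered to `n_sexes == 2`.
#' @export
sex_consistent_events <- function(events) {
  events |>
    group_by(.data$trait, .data$parent_id, .data$child_id, .data$clade) |>
    summarise(n_sexes = n_distinct(.data$sex),
              sexes = paste(sort(unique(.data$sex)), collapse = ","),
              .groups = "drop") |>
    filter(.data$n_sexes == 2)
}

#' Plain-text report of reduction events
#'
#' @param events Event table from [detect_reduction_events()].
#' @param threshold The threshold the statuses were classified at (echoed in
#'   the header).
#' @return A character vector of report lines.
#' @export
format_event_report <- function(events, threshold = 0.8) {
  header <- sprintf("Reduction events (r < %g at child, r >= %g at parent):",
                    threshold, threshold)
  if (!nrow(events)) return(c(header, "  none"))
  lines <- events |>
    mutate(line = sprintf(
      "  [%s, %s] edge %d -> %d: r %0.3f -> %0.3f; clade: %s",
      .data$sex, .data$trait, .data$parent_id, .data$child_id,
      .data$r_parent, .data$r_child, .data$clade
    )) |>
    pull("line")
  c(header, lines)
}
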