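#' Pairwise limb-length panels with isometry and threshold lines
#'
#' One trait at a time, three panels: T1 vs T2, T1 vs T3, T2 vs T3, all in
#' mm, with the comparison limb on the x axis and the focal limb on the y
#' axis. The solid line marks isometry (y = x); the dashed line, drawn only
#' on the two T1 panels, marks the reduction threshold (y = threshold * x),
#' so reduced T1 points fall below it. Points are coloured by family (filled
#' squares for males, open squares for females).
#'
#' @param table A trait table (see [as_trait_table()]).
#' @param trait One of `"femur"`, `"tibia"`, `"tarsus"`, `"total"`.
#' @param threshold Reduction threshold for the dashed reference line.
#' @param families Optional tibble `species`, `family` for the colour key;
#'   defaults to [study_families()] when all species are study taxa.
#' @return A ggplot object.
#' @export
pairwise_limb_plot <- function(table, trait = "total", threshold = 0.8,
                               families = NULL) {
  table <- as_trait_table(table)
  if (!nrow(table)) {
    abort("empty trait table", class = "brushfoot_validation_error")
  }
  trait <- match.arg(trait, TRAITS)
  if (is.null(families) && all(table$species %in% study_families()$species)) {
    families <- study_families()
  }
  col <- paste0(trait, "_mm")
  wide <- table |>
    select(all_of(c("species", "sex", "limb", col))) |>
    pivot_wider(names_from = "limb", values_from = all_of(col))
  panels <- tibble(
    panel = factor(c("T1 vs T2", "T1 vs T3", "T2 vs T3"),
                   levels = c("T1 vs T2", "T1 vs T3", "T2 vs T3")),
    xlimb = c("T2", "T3", "T3"),
    ylimb = c("T1", "T1", "T2"),
    has_threshold = c(TRUE, TRUE, FALSE)
  )
  pts <- bind_rows(lapply(seq_len(nrow(panels)), function(i) {
    tibble(panel = panels$panel[i],
           species = wide$species, sex = wide$sex,
           x_mm = wide[[panels$xlimb[i]]], y_mm = wide[[panels$ylimb[i]]])
  }))
  if (!is.null(families)) {
    pts <- left_join(pts, families, by = "species")
  } else {
    pts$family <- pts$species
  }
  thresh_lines <- filter(panels, .data$has_threshold)
  p <- ggplot(pts, aes(x = .data$x_mm, y = .data$y_mm)) +
    geom_abline(slope = 1, intercept = 0, linewidth = 0.4) +
    geom_abline(data = thresh_lines, aes(slope = threshold, intercept = 0),
                linetype = "dashed", linewidth = 0.4) +
    geom_point(aes(colour = .data$family, shape = .data$sex), size = 2.2) +
    scale_shape_manual(values = c(male = 15, female = 0)) +
    facet_wrap(~panel, nrow = 1) +
    labs(x = "comparison limb length (mm)", y = "focal limb length (mm)",
         colour = "family", shape = "sex",
         title = sprintf("%s length: pairwise limb comparisons", trait),
         subtitle = sprintf(
           "solid line: isometry; dashed line: %g%% reduction threshold (T1 panels only)",
           100 * threshold)) +
    theme_minimal()
  p
}

#' Wide per-node ancestral state report
#'
#' One row per internal node, one column per sex x limb x trait, values in mm
#' at three decimals. Internal nodes are numbered 1, 2, ... in preorder from
#' the root (tips excluded); the raw `node_id` is kept alongside. When `path`
#' is given the table is written as CSV with a leading `#` comment line
#' documenting the numbering; re-running on identical input yields a
#' byte-identical file.
#'
#' @param ancestors Ancestral-state table from [reconstruct_all()].
#' @param tree The `phylo` object the node ids refer to.
#' @param path Optional CSV output path.
#' @param digits Fixed decimal places (default 3).
#' @return The wide tibble (numeric values rounded to `digits`), invisibly
#'   when `path` is given.
#' @export
ancestral_table_report <- function(ancestors, tree, path = NULL, digits = 3) {
  check_phylo(tree)
  if (!nrow(ancestors)) {
    abort("empty ancestral table", class = "brushfoot_validation_error")
  }
  internal_pre <- preorder_nodes(tree)
  internal_pre <- internal_pre[internal_pre > ape::Ntip(tree)]
  wide <- ancestors |>
    filter(.data$type == "internal") |>
    mutate(column = paste(.data$sex, .data$limb, .data$trait, "mm", sep = "_")) |>
    pivot_wider(id_cols = "node_id", names_from = "column",
                values_from = "value_mm") |>
    mutate(node_number = match(.data$node_id, internal_pre)) |>
    arrange(.data$node_number) |>
    select(all_of(c("node_number", "node_id")), everything())
  value_cols <- setdiff(names(wide), c("node_number", "node_id"))
  rounded <- wide
  rounded[value_cols] <- lapply(rounded[value_cols], round, digits = digits)
  if (!is.null(path)) {
    formatted <- wide
    formatted[value_cols] <- lapply(formatted[value_cols],
                                    function(v) sprintf(paste0("%.", digits, "f"), v))
    lines <- c(
      "# ancestral limb lengths (mm); node_number is preorder over internal nodes from the root, tips excluded",
      readr::format_csv(formatted) |> strsplit("\n") |> unlist()
    )
    readr::write_lines(lines, path)
    return(invisible(rounded))
  }
  rounded
}

#' Pipeline configuration
#'
#' @param tree `"fixture"` for the packaged 13-taxon topology, or a Newick
#'   file path.
#' @param traits `"simulate"` to generate a study-like dataset, or a trait
#'   table CSV path.
#' @param threshold Reduction threshold in (0, 1].
#' @param sexes Sexes to analyse.
#' @param seed Seed for simulation.
#' @param sim Named list of overrides passed to
#'   [generate_study_like_dataset()] (e.g. `sigma`, `femur_factor`).
#' @param weighted Weight squared changes by branch lengths (default off).
#' @param out_dir Optional output directory for CSV/figure artifacts.
#' @param write_figures Also write the pairwise panel figure (default
#'   `FALSE`; all downstream logic rests on the CSV outputs).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tree = "fixture", traits = "simulate",
                            threshold = 0.8, sexes = SEXES, seed = 1,
                            sim = list(), weighted = FALSE,
                            out_dir = NULL, write_figures = FALSE) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("`threshold` must be in (0, 1]", class = "brushfoot_validation_error")
  }
  sexes <- match.arg(sexes, SEXES, several.ok = TRUE)
  structure(
    list(tree = tree, traits = traits, threshold = threshold, sexes = sexes,
         seed = seed, sim = sim, weighted = weighted, out_dir = out_dir,
         write_figures = write_figures),
    class = "pipeline_config"
  )
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "brushfoot_pipeline_error", parent = e)
  })
}

#' Run the full reduction-detection pipeline
#'
#' Read or simulate -> reconstruct all limb/trait surfaces per sex ->
#' relative T1 lengths and threshold classification -> reduction events ->
#' reports. Each stage is logged with row counts; a failing stage raises a
#' `brushfoot_pipeline_error` naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: `tree`, `traits`, `ancestors`, `statuses`,
#'   `events`, `consistent` (sex-consistent events), `report` (text lines),
#'   and `files` (paths written, if `out_dir` was set).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  inform(sprintf("threshold: %g; edge weighting: %s", config$threshold,
                 if (config$weighted) "branch lengths" else "unweighted"))
  tree <- pipeline_stage("tree", {
    if (identical(config$tree, "fixture")) {
      study_tree()
    } else {
      if (!file.exists(config$tree)) {
        abort(sprintf("tree file not found: %s", config$tree),
              class = "brushfoot_io_error")
      }
      parse_newick(paste(readLines(config$tree, warn = FALSE), collapse = ""))
    }
  })
  diag <- validate_tree(tree)
  if (length(diag)) {
    abort(sprintf("pipeline stage 'tree' failed: %s", paste(diag, collapse = "; ")),
          class = "brushfoot_pipeline_error")
  }
  traits <- pipeline_stage("trait table", {
    if (identical(config$traits, "simulate")) {
      do.call(generate_study_like_dataset,
              modifyList(list(seed = config$seed, tree = tree), config$sim))
    } else {
      read_trait_table(config$traits)
    }
  })
  inform(sprintf("trait table: %d rows", nrow(traits)))
  ancestors <- pipeline_stage("reconstruction", {
    reconstruct_all(traits, tree, sexes = config$sexes,
                    weighted = config$weighted)
  })
  inform(sprintf("ancestral states: %d values", nrow(ancestors)))
  statuses <- pipeline_stage("classification", {
    node_relative_lengths(ancestors, threshold = config$threshold)
  })
  inform(sprintf("node statuses: %d (reduced: %d)", nrow(statuses),
                 sum(statuses$reduced)))
  events <- pipeline_stage("event detection", {
    detect_reduction_events(statuses, tree)
  })
  inform(sprintf("reduction events: %d", nrow(events)))
  consistent <- sex_consistent_events(events)
  report <- format_event_report(events, threshold = config$threshold)
  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(config$out_dir,
                       c("ancestral_states.csv", "ancestral_report.csv",
                         "node_status.csv", "reduction_events.csv",
                         "event_report.txt"))
    write_ancestral_table(ancestors, paths[1])
    ancestral_table_report(ancestors, tree, path = paths[2])
    readr::write_csv(statuses, paths[3], progress = FALSE)
    readr::write_csv(select(events, -any_of("child_label")), paths[4],
                     progress = FALSE)
    readr::write_lines(report, paths[5])
    files <- paths
    if (isTRUE(config$write_figures)) {
      fig <- file.path(config$out_dir, "pairwise_limbs.pdf")
      ggsave(fig, pairwise_limb_plot(traits, trait = "total",
                                     threshold = config$threshold),
             width = 9, height = 3.2)
      files <- c(files, fig)
    }
  }
  invisible(list(tree = tree, traits = traits, ancestors = ancestors,
                 statuses = statuses, events = events, consistent = consistent,
                 report = report, files = files))
}
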