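#' Squared-change parsimony reconstruction of a continuous trait
#'
#' Assigns values to internal nodes minimizing the sum of squared changes
#' `S = sum over edges w_e * (value_parent - value_child)^2` with tip values
#' held fixed. In the default unweighted mode every edge has weight 1
#' (changes are not weighted by branch lengths); at the optimum each free
#' node's value equals the (weighted) mean of its graph neighbours, so the
#' solution is the unique harmonic interpolation of the tip values over the
#' tree and is found by one sparse linear solve of that stationarity system.
#' The objective treats the tree as an undirected graph, so reconstructed
#' values do not depend on where the root is placed.
#'
#' Tips with `NA` are treated as free variables (marginalized) by default,
#' preserving tree shape; set `na_action = "error"` for a strict mode.
#'
#' @param tree A `phylo` object.
#' @param x Named numeric vector of tip values (names are tip labels). Tips
#'   absent from `x` or mapped to `NA` are free when `na_action = "free"`.
#' @param weighted If `TRUE`, each squared difference is divided by the branch
#'   length (edge weight `1/length`); requires positive branch lengths on the
#'   tree. Default `FALSE`, matching the unweighted analysis: when the tree
#'   carries branch lengths they are ignored and a classed message
#'   (`brushfoot_branch_lengths_ignored`) is emitted.
#' @param method `"direct"` (sparse linear solve, default) or `"relax"`
#'   (Gauss-Seidel relaxation, a fallback for very large trees).
#' @param tol,max_sweeps Convergence control for `method = "relax"`.
#' @param na_action `"free"` (default) or `"error"` for missing tip values.
#' @param trait,sex Optional labels stored on the fit (bookkeeping only).
#' @return An object of class `scp_fit`: list with `values` (numeric, one per
#'   node id, tips first), `objective` (achieved S), `free` (logical per
#'   node), `tree`, `weighted`, `method`, `trait`, `sex`. Use [tidy()] for a
#'   per-node tibble and [glance()] for a one-row summary.
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' fit <- squared_change_reconstruct(tr, c(A = 0, B = 0, C = 3))
#' tidy(fit)     # inner node 0.6, root 1.8
#' glance(fit)   # objective 3.6
#' @export
squared_change_reconstruct <- function(tree, x, weighted = FALSE,
                                       method = c("direct", "relax"),
                                       tol = 1e-12, max_sweeps = 1e5,
                                       na_action = c("free", "error"),
                                       trait = NULL, sex = NULL) {
  check_phylo(tree)
  method <- match.arg(method)
  na_action <- match.arg(na_action)
  diag <- validate_tree(tree)
  # unary (pass-through) nodes are harmless to the undirected objective and
  # arise naturally when a tree is re-rooted; tolerate them here
  diag <- diag[!grepl("^unary internal node", diag)]
  if (length(diag)) {
    abort(paste0("invalid tree: ", paste(diag, collapse = "; ")),
          class = "brushfoot_validation_error")
  }
  tips <- tree$tip.label
  if (is.null(names(x))) {
    abort("`x` must be a named vector (names are tip labels)",
          class = "brushfoot_validation_error")
  }
  unknown <- setdiff(names(x), tips)
  if (length(unknown)) {
    abort(paste0("tip value(s) for unknown leaf label(s): ",
                 paste(unknown, collapse = ", ")),
          class = "brushfoot_validation_error")
  }
  v <- setNames(rep(NA_real_, length(tips)), tips)
  v[names(x)] <- as.numeric(x)
  if (anyNA(v) && na_action == "error") {
    abort(paste0("missing tip value(s): ",
                 paste(tips[is.na(v)], collapse = ", ")),
          class = "brushfoot_validation_error")
  }
  if (all(is.na(v))) {
    abort("all tip values are missing", class = "brushfoot_validation_error")
  }
  if (any(!is.finite(v[!is.na(v)]))) {
    abort("non-finite tip value(s)", class = "brushfoot_validation_error")
  }
  w <- edge_weights(tree, weighted)
  m <- n_nodes(tree)
  known <- c(unname(v), rep(NA_real_, tree$Nnode))
  values <- switch(method,
    direct = scp_solve_direct(tree$edge, m, known, w),
    relax  = scp_solve_relax(tree$edge, m, known, w, tol, max_sweeps)
  )
  objective <- sum(w * (values[tree$edge[, 1]] - values[tree$edge[, 2]])^2)
  structure(
    list(values = values, objective = objective,
         free = is.na(known), tree = tree, weighted = weighted,
         method = method, trait = trait, sex = sex),
    class = "scp_fit"
  )
}

edge_weights <- function(tree, weighted) {
  if (weighted) {
    if (is.null(tree$edge.length)) {
      abort("weighted mode requires branch lengths on the tree",
            class = "brushfoot_validation_error")
    }
    if (any(!is.finite(tree$edge.length)) || any(tree$edge.length <= 0)) {
      abort("weighted mode requires finite positive branch lengths",
            class = "brushfoot_validation_error")
    }
    1 / tree$edge.length
  } else {
    if (!is.null(tree$edge.length)) {
      inform(
        "branch lengths are present on the tree but ignored: changes are not weighted by branch lengths (use weighted = TRUE to weight them)",
        class = "brushfoot_branch_lengths_ignored"
      )
    }
    rep(1, nrow(tree$edge))
  }
}

scp_solve_direct <- function(edge, m, known, w) {
  free <- which(is.na(known))
  if (!length(free)) return(known)
  A <- Matrix::sparseMatrix(
    i = c(edge[, 1], edge[, 2]),
    j = c(edge[, 2], edge[, 1]),
    x = c(w, w),
    dims = c(m, m)
  )
  deg <- Matrix::rowSums(A)
  fixed <- which(!is.na(known))
  Lff <- Matrix::Diagonal(x = deg[free]) - A[free, free, drop = FALSE]
  b <- A[free, fixed, drop = FALSE] %*% known[fixed]
  known[free] <- as.numeric(Matrix::solve(Lff, b))
  known
}

scp_solve_relax <- function(edge, m, known, w, tol, max_sweeps) {
  free <- which(is.na(known))
  if (!length(free)) return(known)
  # neighbour lists with edge weights
  nbr <- vector("list", m)
  for (k in seq_len(nrow(edge))) {
    a <- edge[k, 1]; b <- edge[k, 2]
    nbr[[a]] <- rbind(nbr[[a]], c(b, w[k]))
    nbr[[b]] <- rbind(nbr[[b]], c(a, w[k]))
  }
  val <- known
  val[free] <- mean(known, na.rm = TRUE)
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (i in free) {
      nb <- nbr[[i]]
      new <- sum(nb[, 2] * val[nb[, 1]]) / sum(nb[, 2])
      delta <- max(delta, abs(new - val[i]))
      val[i] <- new
    }
    if (delta < tol) break
  }
  if (delta >= tol) {
    warn(sprintf("relaxation stopped after %d sweeps with residual %.3g",
                 max_sweeps, delta))
  }
  val
}

#' Brute-force oracle for squared-change parsimony
#'
#' Minimizes the same sum-of-squared-changes objective as
#' [squared_change_reconstruct()] by generic numerical minimization (BFGS with
#' numerical gradients) from several random starting points, entirely
#' independent of the linear-solve path. Intended for verification on small
#' trees (tens of nodes).
#'
#' @inheritParams squared_change_reconstruct
#' @param n_starts Number of random restarts (starting values drawn uniformly
#'   over the observed tip range).
#' @param maxit Iteration cap per start.
#' @return An `scp_fit` (with `method = "oracle"`).
#' @export
oracle_reconstruct <- function(tree, x, weighted = FALSE, n_starts = 5,
                               maxit = 2000) {
  check_phylo(tree)
  tips <- tree$tip.label
  v <- setNames(rep(NA_real_, length(tips)), tips)
  v[names(x)] <- as.numeric(x)
  if (all(is.na(v))) {
    abort("all tip values are missing", class = "brushfoot_validation_error")
  }
  w <- if (weighted) 1 / tree$edge.length else rep(1, nrow(tree$edge))
  m <- n_nodes(tree)
  known <- c(unname(v), rep(NA_real_, tree$Nnode))
  free <- which(is.na(known))
  e1 <- tree$edge[, 1]; e2 <- tree$edge[, 2]
  fn <- function(par) {
    val <- known
    val[free] <- par
    sum(w * (val[e1] - val[e2])^2)
  }
  lo <- min(known, na.rm = TRUE); hi <- max(known, na.rm = TRUE)
  span <- max(hi - lo, 1)
  best <- NULL
  codes <- integer(0)
  for (s in seq_len(n_starts)) {
    par0 <- runif(length(free), lo - 0.1 * span, hi + 0.1 * span)
    opt <- optim(par0, fn, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-15))
    codes <- c(codes, opt$convergence)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (all(codes != 0)) {
    abort(sprintf("oracle failed to converge; best objective found: %.6g",
                  best$value),
          class = "brushfoot_convergence_error")
  }
  values <- known
  values[free] <- best$par
  structure(
    list(values = values, objective = best$value,
         free = is.na(known), tree = tree, weighted = weighted,
         method = "oracle", trait = NULL, sex = NULL),
    class = "scp_fit"
  )
}

#' @export
print.scp_fit <- function(x, ...) {
  cat(sprintf(
    "Squared-change parsimony fit (%s%s): %d tips, %d free node(s), objective %.6g\n",
    x$method, if (x$weighted) ", branch-length weighted" else ", unweighted",
    ape::Ntip(x$tree), sum(x$free), x$objective))
  invisible(x)
}

#' Tidy a squared-change parsimony fit
#'
#' @param x An `scp_fit` from [squared_change_reconstruct()] or
#'   [oracle_reconstruct()].
#' @param ... Unused.
#' @return A tibble with one row per node: `node_id`, `label` (tip label or
#'   `NA`), `type` (`"tip"`/`"internal"`), `free` (was the value estimated),
#'   `value_mm`, plus `trait`/`sex` when set on the fit.
#' @method tidy scp_fit
#' @export
tidy.scp_fit <- function(x, ...) {
  n <- ape::Ntip(x$tree)
  m <- n_nodes(x$tree)
  out <- tibble(
    node_id = seq_len(m),
    label = c(x$tree$tip.label, rep(NA_character_, x$tree$Nnode)),
    type = rep(c("tip", "internal"), c(n, x$tree$Nnode)),
    free = x$free,
    value_mm = x$values
  )
  if (!is.null(x$trait)) out$trait <- x$trait
  if (!is.null(x$sex)) out$sex <- x$sex
  out
}

#' Summarize a squared-change parsimony fit
#'
#' @inheritParams tidy.scp_fit
#' @return One-row tibble: `objective` (achieved sum of squared changes),
#'   `n_tips`, `n_free`, `weighted`, `method`.
#' @method glance scp_fit
#' @export
glance.scp_fit <- function(x, ...) {
  tibble(objective = x$objective, n_tips = ape::Ntip(x$tree),
         n_free = sum(x$free), weighted = x$weighted, method = x$method)
}

#' Plot reconstructed node values
#'
#' Reconstructed (internal) and observed (tip) values in preorder from the
#' root; a quick visual check that the harmonic interpolation stays inside
#' the tip range (maximum principle).
#'
#' @param object An `scp_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scp_fit
#' @export
autoplot.scp_fit <- function(object, ...) {
  ord <- preorder_nodes(object$tree)
  df <- tidy(object)
  df$position <- match(df$node_id, ord)
  ggplot(df, aes(x = .data$position, y = .data$value_mm, shape = .data$type)) +
    geom_hline(yintercept = range(df$value_mm[df$type == "tip"]),
               linetype = "dotted", colour = "grey50") +
    geom_point(size = 2) +
    scale_shape_manual(values = c(tip = 15, internal = 1)) +
    labs(x = "node (preorder from root)", y = "value (mm)",
         shape = NULL,
         title = "Squared-change parsimony reconstruction") +
    theme_minimal()
}

#' Reconstruct every limb and trait surface
#'
#' Runs [squared_change_reconstruct()] independently for each limb (T1, T2,
#' T3) and trait (femur, tibia, tarsus, total) at each requested sex — 12
#' reconstructions per sex — and merges the results, tips (observed) and
#' internal nodes (reconstructed), into one long ancestral-state table. The
#' `total` surface is reconstructed in its own right; because the solver is
#' linear in the tip values, it equals the sum of the three segment surfaces
#' at every node.
#'
#' @param table A trait table (see [as_trait_table()]) covering every tree
#'   leaf for each requested sex and all three limbs.
#' @param tree A `phylo` object whose tip labels match `table$species`.
#' @param sexes Sexes to reconstruct (default both).
#' @param weighted Passed to [squared_change_reconstruct()].
#' @return A tibble with columns `node_id`, `label`, `type`, `sex`, `limb`,
#'   `trait`, `value_mm`, carrying an `objectives` attribute (tibble of the
#'   achieved objective per sex x limb x trait; see
#'   [reconstruction_objectives()]).
#' @export
reconstruct_all <- function(table, tree, sexes = SEXES, weighted = FALSE) {
  check_phylo(tree)
  table <- as_trait_table(table)
  sexes <- match.arg(sexes, SEXES, several.ok = TRUE)
  tips <- tree$tip.label
  # strip branch lengths once so the per-surface solver does not repeat the
  # "ignored" notice 12 times
  if (!weighted && !is.null(tree$edge.length)) {
    inform(
      "branch lengths are present on the tree but ignored: changes are not weighted by branch lengths (use weighted = TRUE to weight them)",
      class = "brushfoot_branch_lengths_ignored"
    )
    tree$edge.length <- NULL
  }
  out <- list()
  objectives <- list()
  for (sx in sexes) {
    sub_sex <- filter(table, .data$sex == sx)
    for (lb in LIMBS) {
      sub <- filter(sub_sex, .data$limb == lb)
      missing_sp <- setdiff(tips, sub$species)
      if (length(missing_sp)) {
        abort(sprintf("trait table is missing %s %s rows for: %s",
                      sx, lb, paste(missing_sp, collapse = ", ")),
              class = "brushfoot_validation_error")
      }
      for (tr in TRAITS) {
        x <- setNames(sub[[paste0(tr, "_mm")]], sub$species)
        fit <- squared_change_reconstruct(tree, x, weighted = weighted,
                                          trait = tr, sex = sx)
        td <- tidy(fit)
        out[[length(out) + 1L]] <- tibble(
          node_id = td$node_id, label = td$label, type = td$type,
          sex = sx, limb = lb, trait = tr, value_mm = td$value_mm
        )
        objectives[[length(objectives) + 1L]] <- tibble(
          sex = sx, limb = lb, trait = tr, objective = fit$objective
        )
      }
    }
  }
  res <- bind_rows(out)
  attr(res, "objectives") <- bind_rows(objectives)
  res
}

#' Achieved objectives of a merged reconstruction
#'
#' @param ancestors The result of [reconstruct_all()].
#' @return A tibble `sex`, `limb`, `trait`, `objective`.
#' @export
reconstruction_objectives <- function(ancestors) {
  obj <- attr(ancestors, "objectives")
  if (is.null(obj)) {
    abort("no objectives attribute: was this produced by reconstruct_all()?",
          class = "brushfoot_validation_error")
  }
  obj
}

#' Write an ancestral-state table to CSV
#'
#' Long format: `node_id`, `sex`, `limb`, `trait`, `value_mm`.
#'
#' @param ancestors The result of [reconstruct_all()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ancestral_table <- function(ancestors, path) {
  readr::write_csv(
    select(ancestors, all_of(c("node_id", "sex", "limb", "trait", "value_mm"))),
    path, progress = FALSE
  )
  invisible(path)
}
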