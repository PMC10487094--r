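# Occurrence thinning, background sampling, collinearity screening and
# train/test partitioning.

#' Spatial thinning of occurrence points
#'
#' Retains at most one point per grid cell; when several points share a
#' cell the survivor is chosen uniformly at random (seeded). Points in
#' distinct cells are untouched. Thinning is idempotent.
#'
#' @param points an [occurrence_set()] or data.frame with `x`, `y`.
#' @param grid the [grid_spec()] defining the thinning cells (typically the
#'   predictor grid).
#' @param seed integer seed.
#' @return An [occurrence_set()] of the surviving points.
#' @export
thin_occurrences <- function(points, grid, seed = 1) {
  if (nrow(points) == 0) stop("cannot thin an empty occurrence set")
  rc <- point_to_cell(grid, points$x, points$y)
  if (anyNA(rc$row)) stop("some points fall outside the thinning grid")
  cell <- (rc$col - 1L) * grid$n_rows + rc$row
  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(points)), cell), function(ix) {
    if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
  }), use.names = FALSE)
  keep <- sort(keep)
  occurrence_set(points$x[keep], points$y[keep],
                 if (points$label[1] == "background") "background" else "presence")
}

#' Uniform background (pseudo-absence) sample
#'
#' Samples `n` distinct cell centres uniformly at random from the grid,
#' excluding cells that contain a point of `exclude` and cells flagged
#' nodata in `mask`.
#'
#' @param grid a [grid_spec()].
#' @param n number of background points (`0` gives an empty set).
#' @param exclude an [occurrence_set()] whose cells are excluded
#'   (typically the presences).
#' @param seed integer seed.
#' @param mask optional `hs_raster` whose nodata cells are excluded.
#' @return An [occurrence_set()] with label `"background"`.
#' @export
sample_background <- function(grid, n, exclude = NULL, seed = 1, mask = NULL) {
  stopifnot(n >= 0)
  ok <- rep(TRUE, grid$n_rows * grid$n_cols)
  if (!is.null(mask)) ok[as.vector(mask$nodata_mask)] <- FALSE
  if (!is.null(exclude) && nrow(exclude) > 0) {
    rc <- point_to_cell(grid, exclude$x, exclude$y)
    drop <- (rc$col - 1L) * grid$n_rows + rc$row
    ok[drop[!is.na(drop)]] <- FALSE
  }
  pool <- which(ok)
  if (n > length(pool))
    stop("n = ", n, " exceeds the ", length(pool), " available background cells")
  set.seed(seed)
  idx <- if (n == 0) integer(0) else pool[sample.int(length(pool), n)]
  row <- (idx - 1) %% grid$n_rows + 1
  col <- (idx - 1) %/% grid$n_rows + 1
  occurrence_set(cell_centers_x(grid)[col], cell_centers_y(grid)[row], "background")
}

#' Greedy collinearity screening of predictors
#'
#' While any pair of remaining predictors has `|r| >= threshold` (Pearson),
#' drops the member of the worst pair with the larger mean absolute
#' correlation to all other remaining predictors. Constant predictors
#' (undefined r) are dropped first with a warning. Predictors named in
#' `keep` are never dropped. Columns flagged as grouped indicator encodings
#' of a categorical variable (attribute `groups` of the table) are kept
#' aside from the screening.
#'
#' @param table a training table from [build_training_table()], or any
#'   data.frame of numeric predictors (a `response` column is ignored).
#' @param threshold pairwise |r| cut-off (default 0.75).
#' @param keep character vector of predictor names protected from dropping
#'   (the "ecologically meaningful" keep-list).
#' @return Character vector of surviving predictor names, in input order.
#' @export
select_predictors <- function(table, threshold = 0.75, keep = character(0)) {
  grouped <- unlist(attr(table, "groups"), use.names = FALSE)
  vars <- setdiff(names(table), c("response", grouped))
  vars <- vars[vapply(table[vars], is.numeric, TRUE)]
  if (length(vars) < 2) stop("need at least 2 predictors to screen")
  if (nrow(table) < 3) stop("need at least 3 rows to estimate correlations")
  const <- vars[vapply(table[vars], function(v) stats::sd(v) == 0, TRUE)]
  if (length(const)) {
    warning("dropping constant predictor(s): ", paste(const, collapse = ", "))
    vars <- setdiff(vars, const)
  }
  surviving <- vars
  repeat {
    if (length(surviving) < 2) break
    r <- abs(stats::cor(table[surviving]))
    diag(r) <- 0
    if (max(r) < threshold) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- surviving[worst]
    mean_r <- rowMeans(r)[worst]
    # drop the pair member with the larger mean |r|; keep-listed names win
    drop <- if (pair[1] %in% keep && pair[2] %in% keep) NA_character_
            else if (pair[1] %in% keep) pair[2]
            else if (pair[2] %in% keep) pair[1]
            else pair[which.max(mean_r)]
    if (is.na(drop)) break   # both protected: leave the pair in place
    surviving <- setdiff(surviving, drop)
  }
  out <- vars[vars %in% surviving]
  c(out, intersect(names(table), grouped_names(table)))
}

grouped_names <- function(table) {
  g <- attr(table, "groups")
  if (is.null(g)) character(0) else unlist(g, use.names = FALSE)
}

#' Stratified train/test split
#'
#' Splits a training table by response class: `round(fraction * n)` rows of
#' each class go to the training partition, the rest to the test partition.
#' The partitions are disjoint and exhaustive. Distinct `run_id`s give
#' distinct partitions under one master seed.
#'
#' @param table a training table (data.frame with `response` in 0/1).
#' @param fraction training fraction (default 0.8). `fraction = 1` yields
#'   an empty test set, flagged with attribute `empty_test`.
#' @param run_id integer run identifier.
#' @param seed master seed.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(table, fraction = 0.8, run_id = 1, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  set.seed(derive_seed(seed, run_id))
  train_idx <- unlist(lapply(split(seq_len(nrow(table)), table$response), function(ix) {
    k <- round(fraction * length(ix))
    if (k == length(ix)) ix else sample(ix, k)
  }), use.names = FALSE)
  train_idx <- sort(train_idx)
  out <- list(train = table[train_idx, , drop = FALSE],
              test = table[setdiff(seq_len(nrow(table)), train_idx), , drop = FALSE])
  for (nm in c("train", "test")) {
    attr(out[[nm]], "groups") <- attr(table, "groups")
    attr(out[[nm]], "predictor_names") <- attr(table, "predictor_names")
  }
  if (nrow(out$test) == 0) attr(out, "empty_test") <- TRUE
  out
}

#' Build a presence-background training table from a stack
#'
#' Extracts predictor values at the presence and background cells. The
#' categorical `lulc` layer is one-hot encoded into indicator columns
#' `lulc_c<code>` (first observed class dropped as the reference level);
#' the encoding is recorded in attributes so prediction uses identical
#' columns. Rows touching nodata are removed.
#'
#' @param stack named list of `hs_raster` layers.
#' @param presences,background [occurrence_set()]s.
#' @param predictors predictor layers to use (default: all in the stack).
#' @return data.frame of predictors plus `response` (1 = presence), with
#'   attributes `predictor_names`, `groups` (categorical name -> indicator
#'   columns) and `encoding` (class levels per categorical layer).
#' @export
build_training_table <- function(stack, presences, background,
                                 predictors = names(stack)) {
  pts <- rbind(data.frame(x = presences$x, y = presences$y, response = 1),
               data.frame(x = background$x, y = background$y, response = 0))
  grid <- stack[[1]]$grid
  rc <- point_to_cell(grid, pts$x, pts$y)
  if (anyNA(rc$row)) stop("some points fall outside the predictor grid")
  idx <- cbind(rc$row, rc$col)
  out <- data.frame(row.names = seq_len(nrow(pts)))
  groups <- list(); encoding <- list()
  drop_rows <- rep(FALSE, nrow(pts))
  for (nm in predictors) {
    lyr <- stack[[nm]]
    vals <- lyr$values[idx]
    drop_rows <- drop_rows | lyr$nodata_mask[idx]
    if (lyr$kind == "categorical") {
      levs <- sort(unique(as.vector(lyr$values[!lyr$nodata_mask])))
      encoding[[nm]] <- levs
      cols <- paste0(nm, "_c", levs[-1])
      for (k in seq_along(levs)[-1]) out[[cols[k - 1]]] <- as.numeric(vals == levs[k])
      groups[[nm]] <- cols
    } else {
      out[[nm]] <- vals
    }
  }
  out$response <- pts$response
  out <- out[!drop_rows, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            predictor_names = predictors,
            groups = groups,
            encoding = encoding)
}

#' Build a whole-stack prediction table
#'
#' Converts every non-nodata cell of a stack into a prediction row using
#' the same one-hot encoding recorded on a training table.
#'
#' @param stack named list of `hs_raster` layers.
#' @param template a table from [build_training_table()] supplying the
#'   encoding.
#' @return List with `data` (data.frame), `cell_index` (vector index of
#'   each row in the grid, column-major) and `grid`.
#' @keywords internal
stack_prediction_frame <- function(stack, template) {
  grid <- stack[[1]]$grid
  encoding <- attr(template, "encoding")
  mask <- Reduce(`|`, lapply(stack, function(l) l$nodata_mask))
  keep <- which(!as.vector(mask))
  out <- data.frame(row.names = seq_along(keep))
  for (nm in attr(template, "predictor_names")) {
    lyr <- stack[[nm]]
    vals <- as.vector(lyr$values)[keep]
    if (lyr$kind == "categorical") {
      levs <- encoding[[nm]]
      for (k in seq_along(levs)[-1])
        out[[paste0(nm, "_c", levs[k])]] <- as.numeric(vals == levs[k])
    } else {
      out[[nm]] <- vals
    }
  }
  list(data = out, cell_index = keep, grid = grid, mask = mask)
}
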