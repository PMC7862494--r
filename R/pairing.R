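#' Centroid distance matrix
#'
#' Euclidean distances between every axon centroid and every fiber
#' centroid, the cost matrix of the axon-to-fiber assignment problem.
#'
#' @param axons,fibers Data frames with columns `centroid_x`, `centroid_y`
#'   (um) and optionally `id`.
#' @return A numeric matrix (axons in rows, fibers in columns, um), with
#'   `dimnames` set from the ids when present.
#' @export
distance_matrix <- function(axons, fibers) {
  for (nm in c("centroid_x", "centroid_y")) {
    if (!nm %in% names(axons) || !nm %in% names(fibers))
      stop(sprintf("both inputs need a `%s` column", nm), call. = FALSE)
  }
  if (nrow(axons) == 0L || nrow(fibers) == 0L)
    stop("centroid sets must be non-empty", call. = FALSE)
  dx <- outer(axons$centroid_x, fibers$centroid_x, `-`)
  dy <- outer(axons$centroid_y, fibers$centroid_y, `-`)
  d <- sqrt(dx^2 + dy^2)
  rownames(d) <- if ("id" %in% names(axons)) as.character(axons$id)
  colnames(d) <- if ("id" %in% names(fibers)) as.character(fibers$id)
  d
}

#' Minimum-cost bipartite assignment (Hungarian method)
#'
#' Solves the rectangular assignment problem: a matching that covers the
#' smaller dimension of `costs` and minimizes the total cost, via the
#' Jonker-Volgenant shortest-augmenting-path formulation of the Hungarian
#' method. Among equal-cost optima the lexicographically smallest
#' (row, column) sequence is returned (the refinement pass that guarantees
#' this is applied for problems with up to 64 rows; exact ties do not arise
#' for continuous centroid data).
#'
#' @param costs Numeric matrix of finite, non-negative costs (rows: axons,
#'   columns: fibers, when used for contour pairing).
#' @return A data frame with columns `row`, `col` (indices into `costs`)
#'   and `cost`, one row per matched pair, ordered by `row`; the attribute
#'   `total_cost` carries the optimal total.
#' @examples
#' optimal_assignment(rbind(c(4, 1, 3), c(2, 0, 5), c(3, 2, 2)))
#' @export
optimal_assignment <- function(costs) {
  if (!is.matrix(costs) || !is.numeric(costs) || any(!is.finite(costs)))
    stop("`costs` must be a numeric matrix with finite entries",
         call. = FALSE)
  if (any(costs < 0))
    stop("`costs` must be non-negative", call. = FALSE)
  transposed <- nrow(costs) > ncol(costs)
  cm <- if (transposed) t(costs) else costs
  sol <- lsap_solve(cm)
  if (nrow(cm) <= 64L) sol <- lsap_canonical(cm, sol)
  rows <- seq_len(nrow(cm))
  if (transposed) {
    out <- data.frame(row = sol, col = rows)
    out <- out[order(out$row), , drop = FALSE]
  } else {
    out <- data.frame(row = rows, col = sol)
  }
  out$cost <- costs[cbind(out$row, out$col)]
  rownames(out) <- NULL
  attr(out, "total_cost") <- sum(out$cost)
  out
}

# Jonker-Volgenant shortest augmenting path; requires nrow <= ncol.
# Returns the assigned column for each row.
lsap_solve <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  u <- numeric(nr); v <- numeric(nc)
  col4row <- rep(NA_integer_, nr)
  row4col <- rep(NA_integer_, nc)
  for (cur in seq_len(nr)) {
    shortest <- rep(Inf, nc)
    prev <- rep(NA_integer_, nc)
    scanned_r <- logical(nr)
    scanned_c <- logical(nc)
    min_val <- 0
    i <- cur
    sink <- NA_integer_
    while (is.na(sink)) {
      scanned_r[i] <- TRUE
      free <- which(!scanned_c)
      d <- min_val + cost[i, free] - u[i] - v[free]
      upd <- d < shortest[free]
      shortest[free[upd]] <- d[upd]
      prev[free[upd]] <- i
      k <- which.min(shortest[free])
      j <- free[k]
      min_val <- shortest[j]
      scanned_c[j] <- TRUE
      if (is.na(row4col[j])) sink <- j else i <- row4col[j]
    }
    u[cur] <- u[cur] + min_val
    oth <- which(scanned_r); oth <- oth[oth != cur]
    if (length(oth))
      u[oth] <- u[oth] + min_val - shortest[col4row[oth]]
    sc <- which(scanned_c)
    v[sc] <- v[sc] - (min_val - shortest[sc])
    j <- sink
    repeat {
      i <- prev[j]
      row4col[j] <- i
      jn <- col4row[i]
      col4row[i] <- j
      if (i == cur) break
      j <- jn
    }
  }
  col4row
}

# Lexicographic tie-break: walk rows in order, fixing the smallest column
# that still permits the optimal total on the remaining subproblem.
lsap_canonical <- function(cost, sol) {
  nr <- nrow(cost); nc <- ncol(cost)
  total <- sum(cost[cbind(seq_len(nr), sol)])
  tol <- 1e-9 * max(1, abs(total))
  fixed <- integer(nr)
  free_cols <- seq_len(nc)
  acc <- 0
  for (i in seq_len(nr)) {
    rest <- if (i < nr) cost[(i + 1L):nr, , drop = FALSE]
    for (j in sort(free_cols)) {
      sub <- acc + cost[i, j]
      if (i < nr) {
        rc <- setdiff(free_cols, j)
        m <- rest[, rc, drop = FALSE]
        s <- lsap_solve(m)
        sub <- sub + sum(m[cbind(seq_len(nrow(m)), s)])
      }
      if (sub <= total + tol) {
        fixed[i] <- j
        acc <- acc + cost[i, j]
        free_cols <- setdiff(free_cols, j)
        break
      }
    }
  }
  fixed
}

#' Pair axon contours to fiber contours and score myelination
#'
#' Matches each inner (axon) record to an outer (fiber) record by
#' minimum-total centroid distance ([optimal_assignment()]) and computes,
#' per retained pair, the G-ratio (`axon_diameter / fiber_diameter`) and
#' myelin thickness (`(fiber_diameter - axon_diameter) / 2`).
#'
#' Pairs whose centroid distance exceeds `max_distance` (by default the
#' fiber's own SAE radius, since the centroid of a correctly matched axon
#' lies inside its fiber) are dropped and reported; with
#' `require_containment = TRUE` and `fiber_contours` supplied, pairs whose
#' axon centroid falls outside the fiber polygon are dropped too. Retained
#' pairs with `g_ratio >= 1` (axon at least as large as its fiber) are kept
#' but flagged `valid = FALSE` and should be excluded from myelin
#' statistics.
#'
#' @param axons,fibers Data frames with columns `id`, `centroid_x`,
#'   `centroid_y`, `sae_diameter` (um), e.g. from [add_sae_columns()].
#' @param max_distance Numeric drop threshold (um), or `NULL` for the
#'   per-fiber default `sae_diameter / 2`.
#' @param require_containment Check axon centroid inside fiber polygon.
#' @param fiber_contours Named list of [contour()]s keyed by fiber id
#'   (needed only when `require_containment = TRUE`).
#' @return Data frame of pairs (`fiber_id`, `axon_id`, `centroid_distance`,
#'   `fiber_diameter`, `axon_diameter`, `g_ratio`, `myelin_thickness`,
#'   `valid`), with attributes `dropped` (data frame of dropped pairs and
#'   reasons) and `unmatched` (ids on the larger side left uncovered).
#' @export
pair_and_score <- function(axons, fibers, max_distance = NULL,
                           require_containment = FALSE,
                           fiber_contours = NULL) {
  need <- c("id", "centroid_x", "centroid_y", "sae_diameter")
  for (nm in need) {
    if (!nm %in% names(axons) || !nm %in% names(fibers))
      stop(sprintf("axon and fiber records need a `%s` column", nm),
           call. = FALSE)
  }
  if (require_containment && is.null(fiber_contours))
    stop("`fiber_contours` is required when `require_containment = TRUE`",
         call. = FALSE)
  d <- distance_matrix(axons, fibers)
  asg <- optimal_assignment(d)
  ax <- axons[asg$row, ]
  fb <- fibers[asg$col, ]
  limit <- if (is.null(max_distance)) fb$sae_diameter / 2 else max_distance
  drop_reason <- rep(NA_character_, nrow(asg))
  too_far <- asg$cost > limit
  drop_reason[too_far] <- "centroid_distance_exceeds_max"
  if (require_containment) {
    for (k in which(!too_far)) {
      ctr <- fiber_contours[[as.character(fb$id[k])]]
      if (is.null(ctr) ||
          !point_in_polygon(ax$centroid_x[k], ax$centroid_y[k],
                            ctr$x, ctr$y))
        drop_reason[k] <- "axon_centroid_outside_fiber"
    }
  }
  keep <- is.na(drop_reason)
  pairs <- data.frame(
    fiber_id = as.character(fb$id[keep]),
    axon_id = as.character(ax$id[keep]),
    centroid_distance = asg$cost[keep],
    fiber_diameter = fb$sae_diameter[keep],
    axon_diameter = ax$sae_diameter[keep],
    stringsAsFactors = FALSE
  )
  pairs$g_ratio <- pairs$axon_diameter / pairs$fiber_diameter
  pairs$myelin_thickness <-
    (pairs$fiber_diameter - pairs$axon_diameter) / 2
  pairs$valid <- pairs$g_ratio < 1
  dropped <- data.frame(
    axon_id = as.character(ax$id[!keep]),
    fiber_id = as.character(fb$id[!keep]),
    centroid_distance = asg$cost[!keep],
    reason = drop_reason[!keep],
    stringsAsFactors = FALSE
  )
  if (nrow(dropped))
    message(sprintf("pair_and_score: dropped %d pair(s): %s",
                    nrow(dropped),
                    paste(unique(dropped$reason), collapse = ", ")))
  unmatched <- if (nrow(axons) <= nrow(fibers)) {
    setdiff(as.character(fibers$id), as.character(fb$id))
  } else {
    setdiff(as.character(axons$id), as.character(ax$id))
  }
  attr(pairs, "dropped") <- dropped
  attr(pairs, "unmatched") <- unmatched
  pairs
}

# Even-odd ray casting; on-boundary points count as inside.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}
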