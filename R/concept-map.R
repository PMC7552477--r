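#' Co-sort similarity matrix
#'
#' Entry (a, b) counts the participants who piled statements a and b
#' together. The matrix is symmetric and its diagonal equals the number of
#' participants. Every participant must have piled every statement exactly
#' once (a partition), otherwise a validation error is raised.
#'
#' @param sortings Long tibble with `participant_id`, `statement_id`,
#'   `pile_id`.
#' @return Integer similarity matrix with statement ids as dimnames.
#' @export
cosort_matrix <- function(sortings) {
  check_columns(sortings, c("participant_id", "statement_id", "pile_id"), "sortings")
  statements <- sort(unique(sortings$statement_id))
  participants <- unique(sortings$participant_id)
  S <- length(statements)
  sim <- matrix(0L, S, S, dimnames = list(statements, statements))
  for (p in participants) {
    sub <- sortings[sortings$participant_id == p, ]
    if (nrow(sub) != S || anyDuplicated(sub$statement_id) ||
        !setequal(sub$statement_id, statements)) {
      abort(sprintf(
        "participant %s does not partition all statements (each statement exactly once)",
        p
      ), class = "outcomepay_validation_error")
    }
    pile <- sub$pile_id[match(statements, sub$statement_id)]
    same <- outer(pile, pile, "==")
    sim <- sim + same
  }
  storage.mode(sim) <- "integer"
  sim
}

#' Nonmetric MDS of co-sort similarities into the plane
#'
#' Converts the co-sort similarity into a dissimilarity (participant count
#' minus similarity) and embeds the statements in two dimensions by
#' nonmetric multidimensional scaling (Kruskal's stress, initialized from
#' the classical metric solution, hence deterministic). Statements that were
#' always piled together (zero dissimilarity) are collapsed onto one point
#' before scaling and share coordinates in the output.
#'
#' @param similarity Symmetric nonnegative matrix from [cosort_matrix()].
#' @return Tibble with `statement_id`, `x`, `y`; the Kruskal stress (in
#'   percent) is attached as the `stress` attribute.
#' @export
scale_to_plane <- function(similarity) {
  if (!is.matrix(similarity) || !isSymmetric(unname(similarity)) ||
      any(similarity < 0)) {
    stop_invalid("similarity", "must be a symmetric nonnegative matrix")
  }
  statements <- rownames(similarity)
  diss <- max(similarity) - similarity
  diag(diss) <- 0
  off <- diss[lower.tri(diss)]
  if (length(off) == 0 || max(off) == 0 || stats::var(off) == 0) {
    abort("degenerate similarity: all statement pairs are equally (dis)similar",
          class = "outcomepay_degenerate_error")
  }
  # collapse zero-dissimilarity groups (always co-sorted statements)
  group <- integer(nrow(diss))
  g <- 0L
  for (i in seq_len(nrow(diss))) {
    if (group[i] == 0L) {
      g <- g + 1L
      group[diss[i, ] == 0 & group == 0L] <- g
    }
  }
  reps <- match(seq_len(g), group)
  d_rep <- diss[reps, reps, drop = FALSE]
  if (length(reps) < 3) {
    # two distinct points: place them on the x axis at their dissimilarity
    coords_rep <- cbind(c(0, d_rep[1, 2]), c(0, 0))[seq_along(reps), , drop = FALSE]
    stress <- 0
  } else {
    fit <- MASS::isoMDS(stats::as.dist(d_rep), k = 2, trace = FALSE)
    coords_rep <- fit$points
    stress <- fit$stress
  }
  coords <- coords_rep[group, , drop = FALSE]
  structure(
    tibble::tibble(statement_id = statements, x = coords[, 1], y = coords[, 2]),
    stress = stress
  )
}

#' Cluster statements from coordinates or co-sort similarity
#'
#' Hierarchical agglomerative clustering (Ward linkage), cut at the
#' requested number of clusters. Deterministic. The input may be either the
#' planar MDS coordinates (the classical concept-mapping pipeline) or the
#' co-sort similarity matrix itself, in which case Ward linkage runs on the
#' co-sort dissimilarity (participant count minus similarity). Clustering
#' the full dissimilarity uses all the sorted information, whereas the
#' two-dimensional plane is a lossy projection (typical stress 20-30%); the
#' pipeline in [concept_map()] therefore clusters on the similarity by
#' default and uses the plane for display.
#'
#' @param x Tibble from [scale_to_plane()] with `statement_id`, `x`, `y`, or
#'   a similarity matrix from [cosort_matrix()].
#' @param n_clusters Number of clusters (at most the number of statements).
#' @return Tibble with `statement_id` and integer `cluster`.
#' @export
cluster_statements <- function(x, n_clusters) {
  n_clusters <- check_positive_int(n_clusters, "n_clusters")
  if (is.matrix(x)) {
    if (n_clusters > nrow(x)) {
      stop_invalid("n_clusters", "cannot exceed the number of statements")
    }
    diss <- max(x) - x
    diag(diss) <- 0
    hc <- hclust(stats::as.dist(diss), method = "ward.D2")
    ids <- rownames(x)
  } else {
    check_columns(x, c("statement_id", "x", "y"), "x")
    if (n_clusters > nrow(x)) {
      stop_invalid("n_clusters", "cannot exceed the number of statements")
    }
    hc <- hclust(dist(x[c("x", "y")]), method = "ward.D2")
    ids <- x$statement_id
  }
  tibble::tibble(
    statement_id = ids,
    cluster = unname(cutree(hc, k = n_clusters))
  )
}

#' Importance-rating summaries per cluster (and sub-cluster)
#'
#' The mean and median importance rating over all (participant, statement)
#' pairs within each cluster, reported to one decimal as in concept-mapping
#' tables; optionally also per sub-cluster nested in each cluster. Empty
#' clusters are flagged with `NA` summaries. Higher ratings are treated as
#' more important.
#'
#' @param ratings Long tibble with `participant_id`, `statement_id`,
#'   `rating` (integers 1-5).
#' @param assignment Tibble with `statement_id`, `cluster`.
#' @param subclusters Optional tibble with `statement_id`, `subcluster`.
#' @return Tibble with `cluster` (and `subcluster` when supplied),
#'   `n_statements`, `n_ratings`, `mean_rating`, `median_rating` (one
#'   decimal).
#' @export
rating_summary <- function(ratings, assignment, subclusters = NULL) {
  check_columns(ratings, c("participant_id", "statement_id", "rating"), "ratings")
  check_columns(assignment, c("statement_id", "cluster"), "assignment")
  if (!all(ratings$rating %in% 1:5)) {
    stop_invalid("rating", "must be integers in 1..5")
  }
  dat <- dplyr::inner_join(ratings, assignment, by = "statement_id")
  groups <- "cluster"
  if (!is.null(subclusters)) {
    check_columns(subclusters, c("statement_id", "subcluster"), "subclusters")
    dat <- dplyr::inner_join(dat, subclusters, by = "statement_id")
    groups <- c("cluster", "subcluster")
  }
  out <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      n_statements = dplyr::n_distinct(.data$statement_id),
      n_ratings = dplyr::n(),
      mean_rating = round(mean(.data$rating), 1),
      median_rating = round(median(.data$rating), 1),
      .groups = "drop"
    )
  empty <- setdiff(unique(assignment$cluster), out$cluster)
  if (length(empty) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      cluster = empty, n_statements = 0L, n_ratings = 0L,
      mean_rating = NA_real_, median_rating = NA_real_
    ))
  }
  dplyr::arrange(out, dplyr::across(dplyr::all_of(groups)))
}

#' Build a concept map from sortings and ratings
#'
#' The full concept-mapping pipeline: co-sort similarity, nonmetric MDS to
#' the plane, Ward clustering, and per-cluster importance summaries.
#'
#' @param sortings Long sorting tibble (`participant_id`, `statement_id`,
#'   `pile_id`).
#' @param ratings Long rating tibble (`participant_id`, `statement_id`,
#'   `rating`).
#' @param n_clusters Number of clusters for the map.
#' @param cluster_on `"similarity"` (default: Ward on the full co-sort
#'   dissimilarity) or `"coordinates"` (classical: Ward on the 2-D plane).
#' @return A `concept_map`: list with `statements` (tibble: `statement_id`,
#'   `x`, `y`, `cluster`), `similarity`, `stress`, and `summary`
#'   (per-cluster ratings).
#' @export
concept_map <- function(sortings, ratings, n_clusters = 7,
                        cluster_on = c("similarity", "coordinates")) {
  cluster_on <- match.arg(cluster_on)
  sim <- cosort_matrix(sortings)
  coords <- scale_to_plane(sim)
  assignment <- cluster_statements(
    if (cluster_on == "similarity") sim else coords, n_clusters
  )
  statements <- dplyr::inner_join(coords, assignment, by = "statement_id")
  summary <- rating_summary(ratings, assignment)
  structure(
    list(
      statements = statements,
      similarity = sim,
      stress = attr(coords, "stress"),
      summary = summary
    ),
    class = "concept_map"
  )
}

#' @export
print.concept_map <- function(x, ...) {
  cat(sprintf(
    "<concept_map> %d statements in %d clusters (stress %.2f)\n",
    nrow(x$statements), dplyr::n_distinct(x$statements$cluster), x$stress
  ))
  print(x$summary)
  invisible(x)
}

#' @rdname concept_map
#' @param x A `concept_map`.
#' @param ... Unused.
#' @export
glance.concept_map <- function(x, ...) {
  tibble::tibble(
    n_statements = nrow(x$statements),
    n_clusters = dplyr::n_distinct(x$statements$cluster),
    stress = x$stress,
    mean_rating = round(mean(x$summary$mean_rating, na.rm = TRUE), 1)
  )
}
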