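two_pile_sortings <- function() {
  tidyr::crossing(
    participant_id = sprintf("FG%02d", 1:12),
    statement_id = sprintf("S%03d", 1:4)
  ) |>
    dplyr::mutate(pile_id = ifelse(statement_id %in% c("S001", "S002"), 1L, 2L))
}

test_that("co-sort counts are exact, symmetric and bounded by participants", {
  srt <- two_pile_sortings()
  sim <- cosort_matrix(srt)
  expect_equal(sim["S001", "S002"], 12L) # all 12 participants co-piled them
  expect_equal(sim["S001", "S003"], 0L)  # never together
  expect_true(all(diag(sim) == 12L))
  expect_identical(sim, t(sim))

  one <- dplyr::filter(srt, participant_id == "FG01")
  sim1 <- cosort_matrix(one)
  expect_equal(sim1["S001", "S002"], 1L)

  srt_noisy <- generate_sortings(sorting_spec(seed = 2))
  simn <- cosort_matrix(srt_noisy$sortings)
  expect_true(all(simn >= 0 & simn <= 12))
  expect_identical(simn, t(simn))
})

test_that("a participant who does not pile every statement is rejected", {
  srt <- two_pile_sortings()
  expect_error(cosort_matrix(srt[-1, ]), "partition",
               class = "outcomepay_validation_error")
  dup <- dplyr::bind_rows(srt, srt[1, ])
  expect_error(cosort_matrix(dup), "partition",
               class = "outcomepay_validation_error")
})

test_that("MDS places always-co-sorted statements at the same point", {
  srt <- generate_sortings(sorting_spec(sort_fidelity = 1, seed = 6))
  sim <- cosort_matrix(srt$sortings)
  coords <- scale_to_plane(sim)
  truth <- srt$statements$true_cluster
  xy <- as.matrix(coords[c("x", "y")])
  # zero dissimilarity within a planted cluster: coordinates coincide
  for (k in unique(truth)) {
    members <- xy[truth == k, , drop = FALSE]
    expect_lt(max(dist(members)), 1e-9)
  }
  # between-cluster distances strictly exceed within-cluster distances
  centroids <- xy[!duplicated(truth), ]
  expect_gt(min(dist(centroids)), 1e-6)
})

test_that("MDS is deterministic and rejects degenerate similarity", {
  srt <- generate_sortings(sorting_spec(seed = 9))
  sim <- cosort_matrix(srt$sortings)
  c1 <- scale_to_plane(sim)
  c2 <- scale_to_plane(sim)
  expect_identical(c1, c2)
  expect_true(is.numeric(attr(c1, "stress")))
  flat <- matrix(3L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_error(scale_to_plane(flat), class = "outcomepay_degenerate_error")
  expect_error(scale_to_plane(matrix(-1, 2, 2)),
               class = "outcomepay_validation_error")
})

test_that("clustering recovers noiseless structure exactly and handles edges", {
  srt <- generate_sortings(sorting_spec(sort_fidelity = 1, seed = 10))
  sim <- cosort_matrix(srt$sortings)
  truth <- srt$statements$true_cluster

  cl_sim <- cluster_statements(sim, 7)
  expect_true(same_partition(cl_sim$cluster, truth))

  coords <- scale_to_plane(sim)
  cl_xy <- cluster_statements(coords, 7)
  expect_true(same_partition(cl_xy$cluster, truth))

  singletons <- cluster_statements(coords, nrow(coords))
  expect_equal(dplyr::n_distinct(singletons$cluster), nrow(coords))
  expect_error(cluster_statements(coords, nrow(coords) + 1),
               class = "outcomepay_validation_error")
})

test_that("the full pipeline recovers planted clusters at fidelity 0.9", {
  srt <- generate_sortings(sorting_spec(
    n_statements = 40, n_participants = 12, n_true_clusters = 7,
    sort_fidelity = 0.9, seed = 12
  ))
  cm <- concept_map(srt$sortings, srt$ratings, n_clusters = 7)
  recovered <- cm$statements$cluster[
    match(srt$statements$statement_id, cm$statements$statement_id)
  ]
  expect_gt(ari(recovered, srt$statements$true_cluster), 0.8)
})

test_that("rating summaries report one-decimal means and medians per cluster", {
  ratings <- tibble::tibble(
    participant_id = c("a", "b", "a", "b", "a", "b", "c"),
    statement_id = c("S1", "S1", "S2", "S2", "S3", "S3", "S3"),
    rating = c(4L, 4L, 3L, 4L, 5L, 1L, 3L)
  )
  assignment <- tibble::tibble(
    statement_id = c("S1", "S2", "S3"), cluster = c(1L, 1L, 2L)
  )
  out <- rating_summary(ratings, assignment)
  expect_equal(out$mean_rating[out$cluster == 2], 3.0)
  expect_equal(out$median_rating[out$cluster == 2], 3.0)
  c1 <- dplyr::filter(
    rating_summary(ratings[1:4, ], assignment[1:2, ]), cluster == 1
  )
  expect_equal(c1$mean_rating, 3.8) # mean of {4,4,3,4} to one decimal
  expect_equal(c1$median_rating, 4)

  pair <- rating_summary(
    tibble::tibble(participant_id = c("a", "b"), statement_id = "S1",
                   rating = c(3L, 4L)),
    tibble::tibble(statement_id = "S1", cluster = 1L)
  )
  expect_equal(pair$mean_rating, 3.5)
  expect_equal(pair$median_rating, 3.5)

  # invariant to participant ordering
  shuffled <- rating_summary(ratings[rev(seq_len(nrow(ratings))), ], assignment)
  expect_equal(shuffled, out)

  expect_error(
    rating_summary(dplyr::mutate(ratings, rating = rating + 10), assignment),
    class = "outcomepay_validation_error"
  )
})

test_that("subcluster summaries nest inside clusters and flag empty clusters", {
  srt <- generate_sortings(sorting_spec(seed = 15))
  assignment <- tibble::tibble(
    statement_id = srt$statements$statement_id,
    cluster = srt$statements$true_cluster
  )
  sub <- tibble::tibble(
    statement_id = srt$statements$statement_id,
    subcluster = rep(1:2, length.out = nrow(srt$statements))
  )
  out <- rating_summary(srt$ratings, assignment, sub)
  expect_true(all(c("cluster", "subcluster") %in% names(out)))
  expect_true(all(out$mean_rating >= 1 & out$mean_rating <= 5))

  with_empty <- dplyr::bind_rows(
    assignment, tibble::tibble(statement_id = "GHOST", cluster = 99L)
  )
  out2 <- rating_summary(srt$ratings, with_empty)
  expect_true(is.na(out2$mean_rating[out2$cluster == 99]))
})
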