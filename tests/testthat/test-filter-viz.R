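test_that("single-end filtering is inclusive at the threshold", {
  results <- list(mock_result("a", 95, TRUE), mock_result("b", 94.9, TRUE),
                  mock_result("c", 100, FALSE))
  kept <- apply_filters(results, filter_settings(min_alpha = 95))
  expect_equal(vapply(kept, `[[`, "", "read_name"), c("a", "c"))
  only_span <- apply_filters(results,
                             filter_settings(min_alpha = 0,
                                             spanning_only = TRUE))
  expect_equal(vapply(only_span, `[[`, "", "read_name"), c("a", "b"))
  # the identity filter retains everything
  expect_length(apply_filters(results, filter_settings()), 3L)
})

test_that("a pair is dropped unless both mates pass the score threshold", {
  pair <- list(mock_result("p", 96, TRUE, mate = 1L),
               mock_result("p", 80, FALSE, mate = 2L))
  kept <- apply_filters(pair, filter_settings(min_alpha = 95, paired = TRUE))
  expect_length(kept, 0L)
  kept2 <- apply_filters(pair, filter_settings(min_alpha = 80, paired = TRUE))
  expect_length(kept2, 2L)
  # under spanning-only, one spanning mate suffices
  kept3 <- apply_filters(pair, filter_settings(min_alpha = 0,
                                               spanning_only = TRUE,
                                               paired = TRUE))
  expect_length(kept3, 2L)
  nospan <- list(mock_result("q", 99, FALSE, mate = 1L),
                 mock_result("q", 99, FALSE, mate = 2L))
  expect_length(apply_filters(nospan,
                              filter_settings(spanning_only = TRUE,
                                              paired = TRUE)), 0L)
})

test_that("filtering matches an independent predicate scan on random results", {
  set.seed(83)
  results <- lapply(1:100, function(i)
    mock_result(sprintf("r%03d", i), round(stats::runif(1, 0, 100), 1),
                stats::runif(1) < 0.4))
  for (thr in c(0, 50, 95, 100)) {
    for (span in c(FALSE, TRUE)) {
      kept <- apply_filters(results, filter_settings(thr, span))
      oracle <- Filter(function(r)
        r$alpha >= thr && (!span || r$spanning), results)
      expect_identical(vapply(kept, `[[`, "", "read_name"),
                       vapply(oracle, `[[`, "", "read_name"))
    }
  }
})

test_that("raising the threshold never adds reads", {
  set.seed(89)
  results <- lapply(1:200, function(i)
    mock_result(sprintf("r%03d", i), stats::runif(1, 0, 100),
                stats::runif(1) < 0.5))
  prev <- vapply(apply_filters(results, filter_settings(0)), `[[`, "",
                 "read_name")
  for (thr in seq(10, 100, by = 10)) {
    cur <- vapply(apply_filters(results, filter_settings(thr)), `[[`, "",
                  "read_name")
    expect_true(all(cur %in% prev), info = sprintf("threshold %d", thr))
    prev <- cur
  }
})

test_that("reference colors are unique, deterministic and label-bound", {
  loc <- worked_example_locus()
  panel <- build_reference_panel(loc$source, loc$exons, loc$bp)
  cols <- assign_colors(panel)
  expect_length(cols, 8L)
  expect_equal(anyDuplicated(cols), 0L)
  expect_identical(cols, assign_colors(panel))
  # permuting the panel permutes positions, not label->color pairs
  perm <- reference_panel(left = rev(panel$left), right = rev(panel$right))
  cols_perm <- assign_colors(perm)
  expect_identical(cols[sort(names(cols))], cols_perm[sort(names(cols_perm))])
  # oversized panels cycle with shade variation
  big <- reference_panel(
    left = stats::setNames(replicate(10, rand_seq(8L)), paste0("L", 1:10)),
    right = stats::setNames(replicate(10, rand_seq(8L)), paste0("R", 1:10)))
  expect_warning(big_cols <- assign_colors(big), "palette")
  expect_equal(anyDuplicated(big_cols), 0L)
})

test_that("track layout orders groups and co-plots mates", {
  panel <- reference_panel(left = c(L1 = "ACGTACGTAC"),
                           right = c(R1 = "TTGGCCAATT"))
  res <- list(
    mock_result("span_lo", 90, TRUE, left = "L1", right = "R1"),
    mock_result("left_only", 99, FALSE, left = "L1", right = NA_character_),
    mock_result("span_hi", 99, TRUE, left = "L1", right = "R1"),
    mock_result("right_only", 95, FALSE, left = NA_character_, right = "R1"))
  plot <- layout_tracks(res, panel, filter_settings())
  first_rows <- plot$tracks[!duplicated(plot$tracks$row), ]
  expect_equal(first_rows$name,
               c("span_hi", "span_lo", "left_only", "right_only"))
  # a spanning read contributes exactly two colored segments
  expect_equal(sum(plot$tracks$name == "span_hi"), 2L)
  # empty input still yields a legend-only model
  empty <- layout_tracks(list(), panel, filter_settings())
  expect_equal(empty$n_tracks, 0L)
  expect_equal(nrow(empty$legend), 2L)
  # paired: mates share one row, disjoint mates get a connector
  pair <- list(mock_result("p", 99, FALSE, left = "L1", right = NA_character_,
                           mate = 1L, left_off = c(-9L, -4L)),
               mock_result("p", 97, FALSE, left = NA_character_, right = "R1",
                           mate = 2L, right_off = c(4L, 9L)))
  pp <- layout_tracks(pair, panel, filter_settings(paired = TRUE))
  expect_equal(pp$n_tracks, 1L)
  expect_equal(unique(pp$tracks$row), 1L)
  expect_equal(nrow(pp$connectors), 1L)
})

test_that("rendering is structurally faithful and byte-stable", {
  panel <- reference_panel(left = c(L1 = "ACGTACGTAC"),
                           right = c(R1 = "TTGGCCAATT"))
  res <- lapply(1:10, function(i)
    mock_result(sprintf("r%02d", i), 90 + i, i %% 2 == 0, left = "L1",
                right = "R1"))
  dir <- withr::local_tempdir()
  plot <- layout_tracks(res, panel, filter_settings())
  paths <- render_report(plot, res, dir, basename = "rep")
  svg <- readLines(paths[["svg"]])
  expect_equal(sum(grepl("class=\"read-track\"", svg)), 10L)
  expect_equal(sum(grepl("class=\"legend-entry\"", svg)), 2L)
  expect_equal(sum(grepl("class=\"breakpoint-guide\"", svg)), 1L)
  tsv <- utils::read.delim(paths[["tsv"]])
  expect_equal(nrow(tsv), 10L)
  # deterministic bytes on re-render
  dir2 <- withr::local_tempdir()
  paths2 <- render_report(plot, res, dir2, basename = "rep")
  expect_identical(readLines(paths[["svg"]]), readLines(paths2[["svg"]]))
  expect_identical(readLines(paths[["html"]]), readLines(paths2[["html"]]))
  # TSV row count equals the filtered result count for a non-trivial filter
  kept <- apply_filters(res, filter_settings(min_alpha = 95))
  plot_k <- layout_tracks(kept, panel, filter_settings())
  paths_k <- render_report(plot_k, kept, dir, basename = "kept")
  expect_equal(nrow(utils::read.delim(paths_k[["tsv"]])), length(kept))
})
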