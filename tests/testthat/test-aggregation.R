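score_table <- function(cells) {
  dplyr::bind_rows(lapply(seq_along(cells), function(i) {
    tibble::tibble(index = paste0("i", i), dataset = "d",
                   algorithm = names(cells[[i]]), S = unname(cells[[i]]))
  }))
}

test_that("ORS: best algorithm has ranking 1, ties get fractional ranks", {
  tab <- score_table(list(c(A = 0.9, B = 0.5, C = 0.7)))
  ors <- compute_ors(tab)
  expect_identical(ors$ors[match(c("A", "C", "B"), ors$algorithm)], c(1, 2, 3))
  # two cells, no ties: rank sum = 2 * (1 + 2 + 3)
  tab2 <- score_table(list(c(A = 0.9, B = 0.5, C = 0.7), c(A = 1, B = 3, C = 2)))
  expect_identical(sum(compute_ors(tab2)$ors), 12)
  # ties
  tab3 <- score_table(list(c(A = 0.9, B = 0.9, C = 0.1)))
  ors3 <- compute_ors(tab3)
  expect_identical(ors3$ors[match(c("A", "B", "C"), ors3$algorithm)], c(1.5, 1.5, 3))
})

test_that("rank sums are conserved on random tables, with and without ties", {
  set.seed(31)
  for (trial in 1:1000) {
    m <- sample(3:8, 1)
    n_cells <- sample(1:4, 1)
    cells <- lapply(seq_len(n_cells), function(i) {
      s <- if (trial %% 2 == 0) {
        sample(1:3, m, replace = TRUE) / 4 # forced ties
      } else {
        stats::runif(m)
      }
      stats::setNames(s, paste0("alg", seq_len(m)))
    })
    ors <- compute_ors(score_table(cells))
    expect_equal(sum(ors$ors), n_cells * m * (m + 1) / 2)
  }
})

test_that("fractional ranking matches a naive per-score count", {
  set.seed(32)
  for (trial in 1:1000) {
    m <- sample(3:7, 1)
    s <- stats::setNames(sample(1:4, m, replace = TRUE) + stats::runif(m) * (trial %% 2),
                         paste0("a", seq_len(m)))
    ors <- compute_ors(score_table(list(s)))
    naive <- vapply(s, function(v) 1 + sum(s > v) + (sum(s == v) - 1) / 2, 0)
    expect_equal(ors$ors[match(names(s), ors$algorithm)], unname(naive))
  }
})

test_that("ONS normalizes per cell to the best score", {
  tab <- score_table(list(c(A = 2, B = 1)))
  ons <- compute_ons(tab)
  expect_identical(ons$ons[match(c("A", "B"), ons$algorithm)], c(1, 0.5))

  tab2 <- score_table(list(c(A = 4, B = 2), c(A = 1, B = 3)))
  ons2 <- compute_ons(tab2)
  expect_equal(ons2$ons[match(c("A", "B"), ons2$algorithm)], c(1 + 1 / 3, 0.5 + 1))

  # an algorithm best in every cell reaches exactly I * J
  tab3 <- score_table(list(c(A = 4, B = 2), c(A = 3, B = 1), c(A = 9, B = 2)))
  ons3 <- compute_ons(tab3)
  expect_identical(ons3$ons[ons3$algorithm == "A"], 3)
})

test_that("normalized scores live in [0, 1] with per-cell maximum 1", {
  set.seed(33)
  for (trial in 1:1000) {
    m <- sample(2:6, 1)
    cells <- lapply(1:2, function(i) stats::setNames(stats::runif(m, 0.1, 5), paste0("a", 1:m)))
    ons <- compute_ons(score_table(cells))
    norm <- attr(ons, "normalized")
    expect_true(all(norm$N >= 0 & norm$N <= 1))
    per_cell_max <- tapply(norm$N, norm$index, max)
    expect_equal(as.numeric(per_cell_max), rep(1, 2))
    # naive reference
    want <- sapply(paste0("a", 1:m), function(a) {
      sum(sapply(cells, function(cell) cell[[a]] / max(cell)))
    })
    expect_equal(ons$ons[match(names(want), ons$algorithm)], unname(want))
  }
})

test_that("negative BLCI scores are mapped to [0, 1] before ONS normalization", {
  tab <- tibble::tibble(index = "blci", dataset = "d",
                        algorithm = c("A", "B"), S = c(0.5, -0.5))
  ons <- compute_ons(tab)
  # (0.5+1)/2 = 0.75, (-0.5+1)/2 = 0.25 -> N = 1 and 1/3
  expect_equal(ons$ons[match(c("A", "B"), ons$algorithm)], c(1, 1 / 3))
  ons_raw <- compute_ons(tab, blci_rescale = FALSE)
  expect_equal(ons_raw$ons[match(c("A", "B"), ons_raw$algorithm)], c(1, -1))
})

test_that("aggregation is equivariant to roster permutation and scale", {
  set.seed(34)
  cells <- list(c(A = 0.3, B = 1.2, C = 0.8), c(A = 2, B = 0.5, C = 0.9))
  tab <- score_table(cells)
  perm <- tab[sample(nrow(tab)), ]
  a <- compute_ors(tab); b <- compute_ors(perm)
  expect_identical(a$ors[match(c("A", "B", "C"), a$algorithm)],
                   b$ors[match(c("A", "B", "C"), b$algorithm)])
  oa <- compute_ons(tab); ob <- compute_ons(perm)
  expect_identical(oa$ons[match(c("A", "B", "C"), oa$algorithm)],
                   ob$ons[match(c("A", "B", "C"), ob$algorithm)])
  scaled <- dplyr::mutate(tab, S = S * 7)
  expect_identical(compute_ors(tab)$ors, compute_ors(scaled)$ors)
})

test_that("failed cells are dropped symmetrically with a warning", {
  tab <- score_table(list(c(A = 0.9, B = 0.5), c(A = 0.7, B = 0.6)))
  tab$S[tab$index == "i2" & tab$algorithm == "B"] <- NA
  expect_warning(ors <- compute_ors(tab), "dropping")
  expect_identical(ors$n_cells[match(c("A", "B"), ors$algorithm)], c(2L, 1L))
})

test_that("render_report writes sorted overall tables, details and summary.json", {
  ds <- generate_complete(synthetic_spec(n_genes = 50, seed = 44))
  cfg <- eval_config(list(d1 = ds$matrix), algorithms = c("zero", "row_average", "knn"),
                     B = 1, percentages = c(0.05, 0.10), master_seed = 7, cpp_k = 3)
  st <- evaluate_study(cfg)
  dir <- withr::local_tempdir()
  files <- render_report(st, dir)
  expect_true(file.exists(file.path(dir, "overall_ors.tsv")))
  expect_true(file.exists(file.path(dir, "overall_ons.tsv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  ors <- utils::read.delim(file.path(dir, "overall_ors.tsv"))
  expect_false(is.unsorted(ors$ors)) # small ORS = good, listed first
  details <- list.files(dir, pattern = "^detail_")
  expect_identical(length(details), 3L * 1L)
  d1 <- utils::read.delim(file.path(dir, details[[1]]))
  expect_identical(d1$rank, sort(d1$rank))
  expect_error(render_report(st, dir, indices = "nope"), "empty report scope")

  # ORS- and ONS-implied orders may disagree; both tables are emitted as-is
  # A wins cell 1 by a mile on magnitude but loses cell 2 narrowly on rank
  tab <- score_table(list(c(A = 10, B = 1, C = 0.5), c(A = 1, B = 1.2, C = 1.1)))
  ors2 <- compute_ors(tab); ons2 <- compute_ons(tab)
  expect_false(identical(ors2$algorithm, ons2$algorithm))
})
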