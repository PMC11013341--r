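test_that("major cutoff switches at the stated pool depth", {
  expect_equal(major_cutoff(26172), 1001L)
  expect_equal(major_cutoff(2173), 100L)
  expect_equal(major_cutoff(9999), 100L)
  expect_equal(major_cutoff(10000), 1001L)
  expect_equal(major_cutoff(c(0, 500000)), c(100L, 1001L))
  expect_error(threshold_rule(large_pool_major_min = 50))
})

test_that("integer percentages round half up and reproduce the published triples", {
  # count/total pairs printed with their integer percentages in the survey
  published <- rbind(
    c(473, 2173, 22), c(169, 2173, 8), c(161, 2173, 7), c(140, 2173, 6),
    c(3709, 10709, 35), c(2396, 10709, 22),
    c(2864, 16316, 18), c(2504, 16316, 15),
    c(3485, 7373, 47),
    c(5828, 26133, 22), c(2331, 26133, 9), c(2095, 26133, 8),
    c(1722, 26133, 7), c(1087, 26133, 4),
    c(7380, 20957, 35), c(1879, 20957, 9), c(1643, 20957, 8),
    c(1124, 20957, 5),
    c(1809, 5263, 34), c(1072, 5263, 20),
    c(2051, 5142, 40), c(447, 5142, 9), c(235, 5142, 5),
    c(3292, 12275, 27),
    c(2234, 9229, 24), c(1691, 9229, 18), c(1319, 9229, 14),
    c(3562, 13553, 26), c(3143, 13553, 23), c(1406, 13553, 10),
    c(1142, 13553, 8),
    c(5561, 26172, 21), c(2763, 26172, 11), c(1928, 26172, 7),
    c(1863, 26172, 7), c(1416, 26172, 5), c(1049, 26172, 4),
    c(5359, 22148, 24), c(3539, 22148, 16),
    c(3153, 15362, 21), c(1732, 15362, 11), c(1041, 15362, 7),
    c(2965, 14946, 20), c(2863, 14946, 19), c(1485, 14946, 10),
    c(1228, 14946, 8),
    c(9301, 25290, 37), c(2889, 25290, 11),
    c(5248, 21628, 24), c(2279, 21628, 11), c(1006, 21628, 5),
    c(364, 1704, 21), c(303, 1704, 18), c(195, 1704, 11),
    c(145, 1704, 9), c(80, 1704, 5))
  expect_equal(integer_percent(published[, 1], published[, 2]),
               as.integer(published[, 3]))
  # rounding edges: halves go up
  expect_equal(integer_percent(1, 200), 1L)    # 0.5 -> 1
  expect_equal(integer_percent(1, 201), 0L)
  expect_equal(integer_percent(0, 5000), 0L)
  expect_equal(integer_percent(5000, 5000), 100L)
  expect_error(integer_percent(1, 0), "positive")
})

test_that("classification reproduces the published major counts", {
  # shallow pool (total 2173): four ribotypes at or above 100 reads
  aeq <- classify_pool(sample_pool("M36", c(473, 169, 161, 140, 90, 60, 40),
                                   total_reads = 2173))
  expect_equal(sum(aeq$ribotypes$status == "major"), 4L)
  expect_equal(aeq$ribotypes$percent[1], 22L)

  # deep pool (total 26172): six ribotypes above 1000 reads, the sixth at 1049
  pra <- classify_pool(sample_pool(
    "23", c(5561, 2763, 1928, 1863, 1416, 1049, 950, 800, 700),
    total_reads = 26172))
  majors <- pra$ribotypes[pra$ribotypes$status == "major", ]
  expect_equal(nrow(majors), 6L)
  expect_equal(min(majors$count), 1049L)
  expect_equal(majors$percent[6], 4L)

  # all counts below the cutoff: no majors
  low <- classify_pool(sample_pool("x", c(99, 50, 10), total_reads = 20000))
  expect_equal(sum(low$ribotypes$status == "major"), 0L)
})

test_that("classification is idempotent, monotone in counts, and percent sums stay within rounding slack", {
  set.seed(19)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    counts <- sort(sample.int(3000, n), decreasing = TRUE)
    pool <- sample_pool(paste0("p", i), counts,
                        sequences = vapply(seq_len(n), function(j)
                          r_random_dna(60), character(1)),
                        total_reads = sum(counts))
    cl <- classify_pool(pool)
    expect_identical(classify_pool(cl)$ribotypes, cl$ribotypes)

    # percent sum within +/- 0.5 per ribotype when counts sum to the total
    s <- sum(cl$ribotypes$percent)
    expect_lte(s, 100 + 0.5 * n)
    expect_gte(s, 100 - 0.5 * n)

    # raising any single count never demotes it
    k <- sample(n, 1)
    raised <- cl$ribotypes$count
    raised[k] <- raised[k] + sample(500, 1)
    pool2 <- sample_pool(paste0("p", i), raised,
                         sequences = cl$ribotypes$sequence,
                         total_reads = sum(raised))
    cl2 <- classify_pool(pool2)
    before <- cl$ribotypes$status[k]
    after <- cl2$ribotypes$status[match(cl$ribotypes$sequence[k],
                                        cl2$ribotypes$sequence)]
    expect_false(before == "major" && after == "minor")
  }
})

test_that("labels follow rank order; duplicate prefixes within a run are rejected", {
  pool <- classify_pool(sample_pool("ae", c(473, 169, 161, 140),
                                    total_reads = 2173))
  lab <- label_ribotypes(pool, "Ae")
  expect_equal(lab$ribotypes$label, c("Ae1", "Ae2", "Ae3", "Ae4"))
  expect_identical(label_ribotypes(pool, "Ae")$ribotypes$label,
                   lab$ribotypes$label)

  empty <- classify_pool(sample_pool("e", integer(0), total_reads = 0))
  expect_equal(nrow(label_ribotypes(empty, "X")$ribotypes), 0L)

  twelve <- classify_pool(sample_pool("t", seq(1200, 100, by = -100),
                                      total_reads = 10000))
  expect_equal(label_ribotypes(twelve, "L")$ribotypes$label,
               paste0("L", 1:12))

  expect_error(label_pools(list(pool, pool), c("Ae", "Ae")), "duplicate")
})

test_that("the bundled survey table reclassifies under the stated rule, flagging its anomalies", {
  tab <- alopecurinae_pools()
  audit <- audit_pool_table(tab)
  flagged <- audit[audit$flag_status, ]
  # exactly one listed major ribotype sits below its depth cutoff (80 reads
  # in a 1704-read pool)
  expect_equal(nrow(flagged), 1L)
  expect_equal(flagged$count, 80L)
  expect_equal(flagged$sample_id, "M17")

  pools <- pools_from_table(tab)
  cl <- classify_pool(pools[["M36"]])
  expect_equal(sum(cl$ribotypes$status == "major"), 4L)
  expect_equal(cl$ribotypes$percent, c(22L, 8L, 7L, 6L))
})

test_that("pool tables and abundance-annotated FASTA round-trip", {
  seqs <- vapply(1:3, function(i) r_random_dna(80), character(1))
  pool <- make_classified_pool("rt", seqs, c(1500, 400, 50), total = 1950)
  d <- tempfile("tab_"); dir.create(d)
  on.exit(unlink(d, recursive = TRUE), add = TRUE)

  tsv <- file.path(d, "pool.tsv")
  write_pool_table(pool, tsv)
  back <- pools_from_table(read_pool_table(tsv))[["rt"]]
  expect_equal(back$ribotypes$count, pool$ribotypes$count)
  expect_equal(back$ribotypes$sequence, pool$ribotypes$sequence)
  expect_equal(back$total_reads, pool$total_reads)

  fa <- file.path(d, "pool.fasta")
  write_pool_fasta(pool, fa)
  expect_true(any(grepl(";size=1500", readLines(fa))))
  back2 <- read_pool_fasta(fa, "rt")
  expect_equal(back2$ribotypes$count, pool$ribotypes$count)
  expect_equal(back2$ribotypes$sequence, pool$ribotypes$sequence)
})
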