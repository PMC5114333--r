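test_that("average relation matches the literal double sum", {
  W <- matrix(0.4, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  diag(W) <- 0
  expect_equal(avg_relation("x", "y", W), 0.4)
  # constant similarity c gives R = c for disjoint sets
  ids <- paste0("r", 1:7)
  Wc <- matrix(0.3, 7, 7, dimnames = list(ids, ids))
  expect_equal(avg_relation(ids[1:3], ids[4:7], Wc), 0.3)
  # random sets, including overlap (identity pairs count 1)
  withr::with_seed(21, {
    for (i in 1:10) {
      Wr <- matrix(runif(49), 7, 7, dimnames = list(ids, ids))
      Wr <- (Wr + t(Wr)) / 2
      a <- sample(ids, 3)
      b <- sample(ids, 4)
      expect_equal(avg_relation(a, b, Wr), avg_relation_brute(a, b, Wr))
    }
  })
  expect_error(avg_relation(character(0), "x", W), "empty")
})

test_that("inter/intra relations behave at the structural extremes", {
  ids <- paste0("r", 1:8)
  part <- list(a = ids[1:4], b = ids[5:8])
  # statistically identical halves: every similarity equal to the identity
  # value 1 gives R(A,B) = R(A,V) = R(B,V), hence inter = 2
  We <- matrix(1, 8, 8, dimnames = list(ids, ids))
  st <- inter_intra(part, ids, We)
  expect_equal(st$inter, 2, tolerance = 1e-9)
  # perfectly separated: zero cross similarities -> inter = 0
  Ws <- matrix(0, 8, 8, dimnames = list(ids, ids))
  Ws[1:4, 1:4] <- 0.6; Ws[5:8, 5:8] <- 0.6
  st2 <- inter_intra(part, ids, Ws)
  expect_equal(st2$inter, 0)
  # scaling the cross block down strictly lowers inter
  Wm <- We; Wm[1:4, 5:8] <- 0.3; Wm[5:8, 1:4] <- 0.3
  st3 <- inter_intra(part, ids, Wm)
  Wl <- We; Wl[1:4, 5:8] <- 0.15; Wl[5:8, 1:4] <- 0.15
  st4 <- inter_intra(part, ids, Wl)
  expect_lt(st4$inter, st3$inter)
  expect_lt(st3$inter, st$inter)
  # all-zero similarities: the identity convention keeps the denominators
  # positive, so the statistic degrades gracefully to inter = 0
  Wd <- matrix(0, 8, 8, dimnames = list(ids, ids))
  st5 <- inter_intra(part, ids, Wd)
  expect_false(st5$degenerate)
  expect_equal(st5$inter, 0)
})

test_that("leading-node selection cuts at the maximum adjacent gap", {
  expect_equal(sort(leading_nodes(c(0.4, 0.35, 0.1, 0.1, 0.05))), c(1L, 2L))
  expect_equal(leading_nodes(1.0), 1L)
  expect_length(leading_nodes(rep(0.2, 5)), 1L)  # tie rule: top child only
  withr::with_seed(31, {
    for (i in 1:200) {
      k <- sample(1:6, 1)
      p <- runif(k); p <- p / sum(p)
      expect_equal(sort(leading_nodes(p)), leading_brute(p))
    }
  })
})

test_that("trial bipartitions recover planted groupings deterministically", {
  pd <- planted_docs(12L, topics = 2L, seed = 41L)
  part <- bipartition(pd$docs, seed = 5L)
  expect_setequal(c(part$a, part$b), names(pd$docs))
  sides <- ifelse(names(pd$docs) %in% part$a, 1L, 2L)
  tab <- table(sides, pd$truth[names(pd$docs)])
  agree <- max(sum(diag(tab)), sum(tab[1, 2], tab[2, 1]))
  expect_equal(agree, length(pd$docs))  # disjoint vocab: exact recovery
  part2 <- bipartition(pd$docs, seed = 5L)
  expect_identical(part$a, part2$a)
  expect_error(bipartition(pd$docs[1:3]), "at least 4")
})

test_that("shrinkage expands separable nodes and stops on homogeneous ones", {
  rc <- run_config(gibbs_iter = 80L, seed = 2L)
  pd2 <- planted_docs(20L, topics = 2L, seed = 43L)  # two disjoint topics
  dec2 <- should_expand(pd2$docs, config = rc, seed = 3L)
  expect_true(dec2$expand)
  pd1 <- planted_docs(40L, topics = 1L, seed = 44L)  # single topic
  dec1 <- should_expand(pd1$docs, config = rc, seed = 3L)
  expect_false(dec1$expand)
  # boundary: inter exactly delta still expands ("larger than" terminates)
  dec_b <- should_expand(pd2$docs, delta = dec2$stats$inter, config = rc,
                         seed = 3L)
  expect_true(dec_b$expand)
  expect_equal(dec_b$stats$inter, dec2$stats$inter)
})

test_that("records are assigned to all and only their leading children", {
  pd <- planted_docs(20L, topics = 3L, seed = 45L)
  model <- fit_topic_model(pd$docs, 3L, seed = 6L)
  members <- assign_records(model)
  expect_setequal(unique(unlist(members)), names(pd$docs))
  # pure records end up in exactly one child
  per_record <- table(unlist(members))
  expect_true(mean(per_record) < 1.2)
  # a half-and-half mixture record joins two children
  mix_doc <- c(pd$docs[["d1_1"]][1:12], pd$docs[["d2_1"]][1:12])
  post <- infer_mixture(model, mix_doc)
  expect_length(leading_nodes(post), 2L)
  # single membership mode
  members1 <- assign_records(model, multi = FALSE)
  expect_equal(sort(table(unlist(members1))), sort(table(unlist(members1))))
  expect_true(all(table(unlist(members1)) == 1L))
})
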