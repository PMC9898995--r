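test_that("moderated t reduces to the pooled t at prior df 0 and handles degenerate genes", {
  v <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
             g2 = c(5, 6, 7, 5, 6, 7))
  colnames(v) <- sprintf("s%d", 1:6)
  em <- make_em(v, setNames(c(rep("LN", 3), rep("control", 3)), colnames(v)))
  res <- moderated_t_test(em, "LN", "control", prior_df = 0)
  expect_equal(res$logfc[1], -3)
  expect_equal(res$t_mod[1], -3.674, tolerance = 1e-3)  # hand pooled t
  # identical groups: logfc 0, p 1
  expect_equal(res$logfc[2], 0)
  expect_equal(res$p[2], 1)
  # prior-df = 0 agrees with t.test's pooled variant on random data
  em2 <- sim_two_group(20, 5, 5, seed = 4)
  r2 <- moderated_t_test(em2, "LN", "control", prior_df = 0)
  pt <- apply(em2$values, 1, function(x)
    t.test(x[1:5], x[6:10], var.equal = TRUE)$p.value)
  expect_equal(r2$p, unname(pt), tolerance = 1e-12)
  # zero-variance gene floored with a warning
  v3 <- rbind(flat = rep(5, 6), g = rnorm(6))
  colnames(v3) <- colnames(v)
  em3 <- make_em(v3, em$labels)
  expect_warning(moderated_t_test(em3, "LN", "control"), "zero-variance")
})

test_that("empirical-Bayes moderation agrees with the limma oracle", {
  skip_if_not_installed("limma")
  em <- sim_two_group(300, 6, 6, shift_genes = sprintf("g%04d", 1:20),
                      shift = 1.5, seed = 9)
  mine <- moderated_t_test(em, "LN", "control")
  design <- cbind(1, as.integer(em$labels == "LN"))
  fit <- limma::eBayes(limma::lmFit(em$values, design))
  expect_equal(mine$logfc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(mine$t_mod, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(mine$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("moderated-t p-values are calibrated under the null", {
  em <- sim_two_group(1000, 10, 10, seed = 31)
  res <- moderated_t_test(em, "LN", "control")
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.02)
  # and BH leaves essentially nothing significant
  expect_lt(mean(res$q < 0.05), 0.01)
})

test_that("BH adjustment matches the hand step-up computation and is permutation-stable", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- c(0.001, 0.2, 0.03, 0.9, 0.04)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("DEG set intersection obeys inclusion-exclusion and handles edge cases", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = c("c", "e"))
  vs <- intersect_deg_sets(sets)
  expect_equal(vs$common, "c")
  expect_equal(sum(vs$regions$n), length(unique(unlist(sets))))
  # pairwise sizes consistent
  expect_equal(vs$pairwise$n[vs$pairwise$set1 == "A" & vs$pairwise$set2 == "B"], 2L)
  # identical sets
  same <- intersect_deg_sets(list(X = c("a", "b"), Y = c("a", "b")))
  expect_setequal(same$common, c("a", "b"))
  # disjoint sets
  disj <- intersect_deg_sets(list(X = "a", Y = "b"))
  expect_length(disj$common, 0)
  expect_true(all(disj$pairwise$n == 0))
  expect_error(intersect_deg_sets(list(A = "x")), ">= 2")
})

test_that("logFC concordance equals Spearman's rho on shared genes", {
  a <- tibble::tibble(gene = c("a", "b", "c"), logfc = c(1, 2, 3))
  expect_equal(logfc_concordance(a, a), 1)
  b <- a; b$logfc <- -a$logfc
  expect_equal(logfc_concordance(a, b), -1)
  b2 <- tibble::tibble(gene = c("a", "b", "c"), logfc = c(3, 1, 2))
  expect_equal(logfc_concordance(a, b2), -0.5)
  expect_error(logfc_concordance(a, tibble::tibble(gene = c("a", "z"), logfc = 1:2)),
               "shared genes")
})

test_that("label-inconsistent samples are flagged by 2-cut hierarchical clustering", {
  genes <- sprintf("g%04d", 1:40)
  em <- sim_two_group(40, 10, 10, shift_genes = genes[1:30], shift = 8,
                      sd = 1, seed = 5)
  # consistent labels: nothing flagged
  expect_length(flag_mislabeled_samples(em, genes), 0)
  # relabel one case sample as control: exactly that sample flagged
  bad <- em
  bad$labels[3] <- "control"
  expect_equal(flag_mislabeled_samples(bad, genes), names(bad$labels)[3])
  # removing it makes flagging idempotent
  cleaned <- lnflare:::em_subset(bad, samples = setdiff(names(bad$labels),
                                                        names(bad$labels)[3]))
  expect_length(flag_mislabeled_samples(cleaned, genes), 0)
  # shuffled labels draw a warning
  shuf <- em
  shuf$labels[] <- withr::with_seed(8, sample(shuf$labels))
  expect_warning(flag_mislabeled_samples(shuf, genes), "shuffled|majority")
})

test_that("planted DEGs are recovered with high sensitivity across seeds", {
  # conditions: effect 2, noise SD 0.5, 30/30 samples; two-sample t as oracle
  sens_mod <- sens_t <- numeric(20)
  for (i in 1:20) {
    planted <- sprintf("g%04d", 1:40)
    em <- sim_two_group(400, 30, 30, shift_genes = planted, shift = 2,
                        sd = 0.5, seed = 100 + i)
    res <- moderated_t_test(em, "LN", "control")
    sens_mod[i] <- mean(res$q[res$gene %in% planted] < 0.05)
    p_t <- apply(em$values, 1, function(x)
      t.test(x[1:30], x[31:60], var.equal = TRUE)$p.value)
    sens_t[i] <- mean(bh_adjust(p_t)[rownames(em$values) %in% planted] < 0.05)
  }
  expect_gte(mean(sens_mod), 0.95)
  # moderation should not do worse than the plain-t oracle
  expect_gte(mean(sens_mod), mean(sens_t) - 0.01)
})
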