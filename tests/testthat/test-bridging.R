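test_that("closed-form spectra: two-node link and three-node unit path", {
  net2 <- toy_network(matrix(c(0, 1, 1, 0), 2, 2))
  sp2 <- normalized_laplacian(net2)
  expect_equal(sp2$matrix, matrix(c(1, -1, -1, 1), 2, 2))
  expect_equal(sp2$eigenvalues, c(0, 2))
  expect_equal(sp2$n_zero, 1)
  expect_equal(softness(sp2), 0.5)

  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  sp3 <- normalized_laplacian(toy_network(path3))
  expect_equal(sp3$eigenvalues, c(0, 1, 2))
  expect_equal(softness(sp3), 1.5)
})

test_that("zero eigenvalues count connected components and are omitted from softness", {
  two_pairs <- matrix(0, 4, 4)
  two_pairs[1, 2] <- two_pairs[2, 1] <- 1
  two_pairs[3, 4] <- two_pairs[4, 3] <- 1
  sp <- normalized_laplacian(toy_network(two_pairs))
  expect_equal(sp$n_zero, 2)
  expect_equal(softness(sp), 1.0)

  # isolated node contributes its own exact zero eigenvalue
  iso <- matrix(0, 3, 3)
  iso[1, 2] <- iso[2, 1] <- 1
  spi <- normalized_laplacian(toy_network(iso))
  expect_equal(spi$n_zero, 2)
  expect_equal(spi$matrix[3, 3], 0)
  expect_equal(softness(spi), 0.5)

  expect_error(normalized_laplacian(toy_network(matrix(0, 3, 3))),
               "empty network")
})

test_that("node deletion removes exactly the non-bonded couplings and is idempotent", {
  n <- 4
  bonded <- chain_bonded(n)
  sigma <- matrix(0, n, n)
  sigma[1, 2] <- sigma[2, 1] <- 0.9
  sigma[2, 3] <- sigma[3, 2] <- 0.9
  sigma[3, 4] <- sigma[4, 3] <- 0.9
  sigma[1, 3] <- sigma[3, 1] <- 0.5
  sigma[1, 4] <- sigma[4, 1] <- 0.25
  net <- toy_network(sigma, bonded)
  del <- delete_node_couplings(net, 1)
  expect_equal(del$coupling[1, 3], 0)
  expect_equal(del$coupling[4, 1], 0)
  expect_equal(del$coupling[1, 2], 0.9)  # bonded retained
  expect_equal(del$coupling[2, 3], 0.9)  # untouched elsewhere
  expect_equal(delete_node_couplings(del, 1)$coupling, del$coupling)

  # a node with only bonded couplings leaves the network unchanged
  pure <- toy_network(sigma * ifelse(bonded, 1, 0), bonded)
  expect_equal(delete_node_couplings(pure, 2)$coupling, pure$coupling)
})

test_that("a pure covalent chain scores zero everywhere", {
  n <- 7
  bonded <- chain_bonded(n)
  sigma <- ifelse(bonded, 0.8, 0)
  pr <- bridging_profile(toy_network(sigma, bonded))
  expect_equal(pr$scores, rep(0, n))
  expect_false(any(pr$disconnects))
})

test_that("the six-node worked network matches the brute-force oracle", {
  n <- 6
  bonded <- chain_bonded(n)
  sigma <- ifelse(bonded, 1, 0)
  sigma[2, 5] <- sigma[5, 2] <- 1
  sigma[3, 6] <- sigma[6, 3] <- 0.5
  net <- toy_network(sigma, bonded)
  pr <- bridging_profile(net)
  expect_lt(max(abs(pr$scores - oracle_bridging(sigma, bonded))), 1e-8)
})

test_that("bridging scores match the oracle on random connected networks", {
  set.seed(99)
  for (i in 1:25) {
    net <- random_network(sample(5:30, 1))
    pr <- bridging_profile(net)
    expect_lt(max(abs(pr$scores - oracle_bridging(net$coupling, net$bonded))),
              1e-8)
  }
})

test_that("the zero count always equals the component count of the coupling graph", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    sigma <- matrix(0, n, n)
    links <- which(upper.tri(sigma) & runif(n * n) < 0.12, arr.ind = TRUE)
    for (r in seq_len(nrow(links))) {
      w <- runif(1)
      sigma[links[r, 1], links[r, 2]] <- w
      sigma[links[r, 2], links[r, 1]] <- w
    }
    if (all(sigma == 0)) next
    sp <- normalized_laplacian(toy_network(sigma))
    g <- igraph::graph_from_adjacency_matrix(sigma > 0, mode = "undirected")
    expect_equal(sp$n_zero, igraph::components(g)$no)
  }
})

test_that("relabeling residues permutes the scores identically", {
  set.seed(31)
  net <- random_network(12)
  pr <- bridging_profile(net)
  perm <- sample(12)
  pnet <- toy_network(net$coupling[perm, perm], net$bonded[perm, perm],
                      net$residues[perm, ])
  ppr <- bridging_profile(pnet)
  expect_equal(ppr$scores, pr$scores[perm], tolerance = 1e-10)
})

test_that("scores are invariant under uniform scaling of the couplings", {
  set.seed(13)
  for (c_scale in c(0.05, 3, 250)) {
    net <- random_network(15)
    pr1 <- bridging_profile(net)
    net2 <- net
    net2$coupling <- net$coupling * c_scale
    pr2 <- bridging_profile(net2)
    expect_lt(max(abs(pr1$scores - pr2$scores)), 1e-10)
  }
})

test_that("disconnecting deletions are flagged and maskable", {
  # bonded chain 1-2-3 on chain A; node 4 (chain B) hangs off node 3 by a
  # single non-bonded coupling, so deleting node 3's couplings strands it
  res <- mechbridge:::residue_table(chain_id = c("A", "A", "A", "B"),
                                    seq_number = c(1L, 2L, 3L, 1L),
                                    residue_name = "ALA")
  bonded <- bonded_mask(res)
  sigma <- ifelse(bonded, 1, 0)
  sigma[3, 4] <- sigma[4, 3] <- 1
  net <- toy_network(sigma, bonded, res)
  pr <- bridging_profile(net)
  expect_true(pr$disconnects[3])
  expect_false(pr$disconnects[1])
  masked <- bridging_profile(net, mask_disconnecting = TRUE)
  expect_true(is.na(masked$scores[3]))
  expect_false(is.na(masked$scores[1]))
  expect_equal(masked$scores[1], 0)  # only bonded couplings: nothing deleted
})
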