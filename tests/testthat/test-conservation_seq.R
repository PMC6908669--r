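test_that("column entropy: conserved, split, uniform, gap policies", {
  m <- msa(letters[1:4], c("AAG-", "AAG-", "CAGA", "CAGT"))
  ent <- column_entropy_profile(m, gap_policy = "ignore")
  expect_equal(ent[1], 1)            # AACC
  expect_equal(ent[2], 0)            # AAAA
  expect_equal(ent[3], 0)
  expect_equal(ent[4], 1)            # gaps ignored: A vs T
  ent_s <- column_entropy_profile(m, gap_policy = "symbol")
  expect_equal(ent_s[4], 1.5)        # -, -, A, T: -log2 terms 2*(1/2) + ...
  # uniform 20-symbol column
  m20 <- msa(sprintf("s%02d", 1:20), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_equal(column_entropy_profile(m20)[1], log2(20), tolerance = 1e-12)
  # all-gap column undefined under "ignore"
  mg <- msa(c("a", "b"), c("-A", "-C"))
  eg <- column_entropy_profile(mg, "ignore")
  expect_true(is.na(eg[1]))
  expect_equal(attr(eg, "undefined"), 1L)
  # bounds property
  set.seed(1)
  rows <- replicate(7, paste(sample(c(strsplit("ACDEFGHIK", "")[[1]], "-"),
                                    30, TRUE), collapse = ""))
  ep <- column_entropy_profile(msa(sprintf("r%d", 1:7), rows), "symbol")
  expect_true(all(ep >= 0 & ep <= log2(7) + 1e-12))
})

test_that("Hamming distances: identity, mismatches, gap policies, metric", {
  m <- msa(c("a", "b", "c"), c("ACDE", "ACDE", "ACDF"))
  D <- hamming_distance_matrix(m)
  expect_equal(D$matrix["a", "b"], 0)
  expect_equal(D$matrix["a", "c"], 1)
  Dn <- hamming_distance_matrix(m, normalize = TRUE)
  expect_equal(Dn$matrix["a", "c"], 0.25)
  # "ignore": columns with a gap in either sequence are skipped for the pair
  mg <- msa(c("a", "b"), c("A-CD", "AAC-"))
  Dg <- hamming_distance_matrix(mg, gap_policy = "ignore", normalize = TRUE)
  expect_equal(Dg$matrix["a", "b"], 0)     # only columns 1 and 3 compared
  # metric property under "symbol": all triangle inequalities on 10 random rows
  set.seed(3)
  rows <- replicate(10, paste(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                       "-"), 25, TRUE), collapse = ""))
  Dr <- hamming_distance_matrix(msa(sprintf("t%02d", 1:10), rows))$matrix
  expect_equal(Dr, t(Dr))
  expect_equal(diag(Dr), setNames(rep(0, 10), sprintf("t%02d", 1:10)))
  for (i in 1:10) for (j in 1:10) for (k in 1:10)
    expect_lte(Dr[i, j], Dr[i, k] + Dr[k, j])
})

test_that("UPGMA: hand trace, base case, ultrametric reconstruction", {
  ids <- c("A", "B", "C")
  D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, dimnames = list(ids, ids))
  dm <- structure(list(ids = ids, matrix = D), class = "distance_matrix")
  tr <- upgma_tree(dm)
  # hand UPGMA: A,B join at height 1; C attaches at height 3
  expect_true(ape::is.ultrametric(tr))
  co <- ape::cophenetic.phylo(tr)[ids, ids]
  expect_equal(co["A", "B"], 2)
  expect_equal(co["A", "C"], 6)
  hA <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "A")]
  expect_equal(hA, 1)

  # 2 ids: single cherry at half the distance
  dm2 <- structure(list(ids = c("x", "y"),
                        matrix = matrix(c(0, 5, 5, 0), 2,
                                        dimnames = list(c("x", "y"), c("x", "y")))),
                   class = "distance_matrix")
  tr2 <- upgma_tree(dm2)
  expect_equal(sort(tr2$edge.length), c(2.5, 2.5))

  # ultrametric input reconstructed exactly: take cophenetic distances of a
  # random ultrametric tree as input
  set.seed(5)
  rt <- ape::rcoal(8)
  Du <- ape::cophenetic.phylo(rt)
  dmu <- structure(list(ids = rownames(Du), matrix = Du),
                   class = "distance_matrix")
  tru <- upgma_tree(dmu)
  cou <- ape::cophenetic.phylo(tru)[rownames(Du), colnames(Du)]
  expect_equal(cou, Du, tolerance = 1e-10)

  expect_error(upgma_tree(structure(list(ids = ids,
    matrix = matrix(NA_real_, 3, 3)), class = "distance_matrix")), "NA")
})

test_that("permuting sequences permutes the matrix and keeps the topology", {
  set.seed(9)
  m0 <- simulate_msa(n_seqs = 6, length = 80, conservation = 0.8, seed = 4)
  perm <- sample(6)
  mp <- msa(m0$ids[perm], apply(m0$matrix[perm, ], 1, paste, collapse = ""))
  D0 <- hamming_distance_matrix(m0)
  Dp <- hamming_distance_matrix(mp)
  expect_equal(Dp$matrix[m0$ids, m0$ids], D0$matrix)
  t0 <- upgma_tree(D0); tp <- upgma_tree(Dp)
  expect_equal(ape::dist.topo(ape::unroot(t0), ape::unroot(tp)), 0,
               ignore_attr = TRUE)
})

test_that("region-restricted distances equal brute-force column filtering", {
  m <- msa(c("ref", "s1", "s2"),
           c("A-CDE", "AACDF", "AGCDE"), reference_id = "ref")
  # residues 2 and 4 of a structure numbered from 21 (offset 21)
  keys <- c("A:22:", "A:24:")
  cols <- map_structure_to_alignment(m, keys, offset = 21)
  # ungapped reference positions 2 and 4 are alignment columns 3 and 5
  expect_equal(unname(cols), c(3L, 5L))
  rd <- region_distance_submatrix(m, cols)
  sub <- msa(m$ids, apply(m$matrix[, cols], 1, paste, collapse = ""))
  expect_equal(rd$matrix, hamming_distance_matrix(sub)$matrix)
  # full selection equals the global matrix
  all_cols <- seq_len(5)
  expect_equal(region_distance_submatrix(m, all_cols)$matrix,
               hamming_distance_matrix(m)$matrix)
  # fully conserved single column: zero matrix
  expect_true(all(region_distance_submatrix(m, 1)$matrix == 0))
  # unmappable residue warned and skipped
  expect_warning(map_structure_to_alignment(m, c("A:22:", "A:99:"), 21),
                 "unmappable")
})

test_that("aligned FASTA round-trips and Newick is written", {
  m <- simulate_msa(n_seqs = 5, length = 40, seed = 6)
  fp <- tempfile(fileext = ".fasta")
  write_msa_fasta(m, fp)
  m2 <- read_msa_fasta(fp)
  expect_equal(m2$ids, m$ids)
  expect_equal(m2$matrix, m$matrix, ignore_attr = TRUE)
  tp <- tempfile(fileext = ".nwk")
  write_newick(upgma_tree(hamming_distance_matrix(m)), tp)
  tr <- ape::read.tree(tp)
  expect_setequal(tr$tip.label, m$ids)
})
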