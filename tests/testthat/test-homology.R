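hit_line <- function(q = "q1", s = "t1", pid = 80, len = 100, ev = 1e-20,
                     bit = 150) {
  paste(q, s, pid, len, round(len * (1 - pid / 100)), 0, 1, len, 1, len,
        format(ev, scientific = TRUE), bit, sep = "\t")
}

test_that("the tabular alignment parser round-trips and flags bad lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hit_line(), hit_line(s = "t2", pid = 55.5, bit = 90)), f)
  hits <- parse_blast_tabular(f)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$sseqid, c("t1", "t2"))
  expect_equal(hits$pident, c(80, 55.5))
  expect_equal(hits$bitscore, c(150, 90))
  expect_equal(hits$evalue, c(1e-20, 1e-20))

  writeLines(character(0), f)
  expect_equal(nrow(parse_blast_tabular(f)), 0L)

  writeLines(paste(rep("x", 11), collapse = "\t"), f)
  expect_error(parse_blast_tabular(f), "line 1")
  writeLines(c(hit_line(), sub("150$", "abc", hit_line())), f)
  expect_error(parse_blast_tabular(f), "line 2")
})

test_that("homolog filtering applies the strict identity and e-value cutoffs", {
  hits <- data.frame(
    qseqid = "q", sseqid = c("a", "b", "c", "d", "q"),
    pident = c(65, 60, 40, 40, 100), evalue = c(1e-9, 1e-9, 0.2, 1e-9, 0),
    bitscore = c(200, 180, 100, 120, 400), stringsAsFactors = FALSE)
  out <- filter_homologs(hits, identity_cutoff = 60, evalue_cutoff = 0.1,
                         self = "q")
  # 65% identity removed (more than t1), exactly 60 kept, evalue 0.2
  # removed, self-hit removed
  expect_setequal(out$sseqid, c("b", "d"))

  # several HSPs for one subject collapse to the best bit-score
  dup <- data.frame(qseqid = "q", sseqid = c("a", "a", "b"),
                    pident = 50, evalue = 1e-5,
                    bitscore = c(90, 140, 70), stringsAsFactors = FALSE)
  out <- filter_homologs(dup, 60)
  expect_equal(nrow(out), 2L)
  expect_equal(out$bitscore[out$sseqid == "a"], 140)
})

test_that("bit-score weighted transfer follows the weighted-frequency form", {
  fx <- tiny_annotated()           # g01..g04 -> a1, g05..g08 -> b1
  one <- data.frame(qseqid = "q", sseqid = "g01", bitscore = 50,
                    stringsAsFactors = FALSE)
  s <- alignment_transfer_score(one, fx$annots, "MF")
  expect_equal(unname(s[c("a1", "A", "R")]), c(1, 1, 1))
  expect_false("b1" %in% names(s))

  two <- data.frame(qseqid = "q", sseqid = c("g01", "g05"),
                    bitscore = c(100, 300), stringsAsFactors = FALSE)
  s <- alignment_transfer_score(two, fx$annots, "MF")
  expect_equal(unname(s["b1"]), 0.75)
  expect_equal(unname(s["a1"]), 0.25)
  expect_equal(unname(s["R"]), 1)

  # empty template list: no prediction
  expect_length(alignment_transfer_score(one[0, ], fx$annots, "MF"), 0)
  # unresolvable subject dropped with warning
  bad <- data.frame(qseqid = "q", sseqid = c("g01", "zz"),
                    bitscore = c(10, 10), stringsAsFactors = FALSE)
  expect_warning(s <- alignment_transfer_score(bad, fx$annots, "MF"),
                 "without annotation")
  expect_equal(unname(s["a1"]), 1)
})

test_that("transfer scoring is order/scale invariant, monotone, and matches the oracle", {
  fx <- tiny_annotated()
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(1:6, 1)
    hits <- data.frame(qseqid = "q",
                       sseqid = sample(names(fx$annots$sets$MF), n,
                                       replace = FALSE),
                       bitscore = runif(n, 10, 400),
                       stringsAsFactors = FALSE)
    s <- alignment_transfer_score(hits, fx$annots, "MF")
    o <- oracle_transfer(hits, fx$annots, "MF")
    expect_equal(s[sort(names(s))], o[sort(names(o))])
    expect_true(all(s >= 0 & s <= 1))
    perm <- hits[sample(n), ]
    expect_equal(alignment_transfer_score(perm, fx$annots, "MF")[names(s)],
                 s)
    scaled <- hits; scaled$bitscore <- scaled$bitscore * 7.3
    expect_equal(alignment_transfer_score(scaled, fx$annots,
                                          "MF")[names(s)], s)
    # adding a template annotated with a1 never decreases score(a1)
    plus <- rbind(hits, data.frame(qseqid = "q", sseqid = "g02",
                                   bitscore = 50))
    s2 <- alignment_transfer_score(plus, fx$annots, "MF")
    base <- if ("a1" %in% names(s)) s[["a1"]] else 0
    expect_gte(s2[["a1"]], base)
  }
})

test_that("protein-level transfer maps subjects to genes before scoring", {
  fx <- tiny_annotated()
  id_map <- data.frame(protein_id = paste0("P_", names(fx$annots$sets$MF)),
                       gene_id = names(fx$annots$sets$MF),
                       stringsAsFactors = FALSE)
  hits <- data.frame(qseqid = "P_q", sseqid = c("P_g01", "P_g05"),
                     bitscore = c(80, 20), stringsAsFactors = FALSE)
  s <- psagp_score(hits, id_map, fx$annots, "MF")
  expect_equal(unname(s["a1"]), 0.8)
  # identity mapping reduces to gene-level transfer
  gh <- hits; gh$sseqid <- c("g01", "g05")
  ident <- data.frame(protein_id = c("g01", "g05"),
                      gene_id = c("g01", "g05"))
  expect_equal(psagp_score(gh, ident, fx$annots, "MF"),
               alignment_transfer_score(gh, fx$annots, "MF"))
  # non-coding query: no-prediction signal, distinct from empty hits
  expect_null(psagp_score(hits, id_map, fx$annots, "MF",
                          query_protein = NA))
  expect_length(psagp_score(hits[0, ], id_map, fx$annots, "MF"), 0)
  # unmapped subject dropped with warning
  expect_warning(psagp_score(
    data.frame(qseqid = "P_q", sseqid = c("P_g01", "P_zz"),
               bitscore = c(10, 99)), id_map, fx$annots, "MF"),
    "id map")
})

test_that("the frequency prior is the annotated-gene fraction per term", {
  fx <- tiny_annotated()
  s <- ngp_score(fx$annots, "MF")
  expect_equal(unname(s["R"]), 1)
  expect_equal(unname(s["a1"]), 0.5)
  expect_true(all(s >= 0 & s <= 1))
  expect_error(ngp_score(fx$annots, "BP"), "no annotated genes")

  # 3-of-4 worked case
  dag <- go_dag(c("R", "Q"), list(R = character(0), Q = "R"),
                c(R = "MF", Q = "MF"))
  ann <- data.frame(gene_id = paste0("g", 1:4),
                    go_id = c("Q", "Q", "Q", "R"), aspect = "MF")
  expect_equal(unname(ngp_score(annotation_db(ann, dag), "MF")["Q"]), 0.75)
})

test_that("columnwise identity counts matching positions", {
  expect_equal(naive_pairwise_identity("ACGTACGTAC", "ACGTACGTAC"), 100)
  expect_equal(naive_pairwise_identity("AAAAAAAAAA", "AAAAAATTTT"), 60)
  expect_equal(naive_pairwise_identity("AAAA", "TTTT"), 0)
  expect_error(naive_pairwise_identity("AAA", "AAAA"), "length")
})
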