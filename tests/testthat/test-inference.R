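# two-context fixtures built directly from DE sign patterns

reg3 <- data.frame(tf = c("X", "Y", "Z"), target = c("FASL", "FASL", "Q"),
                   confidence = "C", sign = 0L, stringsAsFactors = FALSE)

test_that("target-regulating TFs intersect regulon and expression per context", {
  cr <- list(A = make_context(c(X = 0, Y = 0, FASL = -2)),
             B = make_context(c(X = 0, Y = 0, FASL = -2)))
  out <- target_regulating_tfs("FASL", reg3, cr)
  expect_identical(out$per_context$A, c("X", "Y"))
  expect_identical(out$shared, c("X", "Y"))

  crB <- cr
  crB$B$expressed <- c("X", "FASL")          # Y not expressed in B
  out2 <- target_regulating_tfs("FASL", reg3, crB)
  expect_identical(out2$shared, "X")

  expect_error(target_regulating_tfs("NOPE", reg3, cr), "absent from regulon")

  # brute-force comparison on random fixtures
  set.seed(14)
  for (i in 1:5) {
    tfs <- sprintf("T%02d", 1:12)
    reg <- data.frame(tf = sample(tfs, 20, TRUE), target = sample(c("FASL", "G1"), 20, TRUE),
                      confidence = "C", sign = 0L, stringsAsFactors = FALSE)
    if (!any(reg$target == "FASL")) next
    expr <- lapply(1:2, function(j) sample(tfs, 8))
    cr_r <- list(A = make_context(setNames(numeric(12), tfs), expressed = expr[[1]]),
                 B = make_context(setNames(numeric(12), tfs), expressed = expr[[2]]))
    got <- target_regulating_tfs("FASL", reg, cr_r)
    brute <- sort(unique(reg$tf[reg$target == "FASL" & reg$tf != "FASL"]))
    expect_identical(got$per_context$A, sort(intersect(brute, expr[[1]])))
    expect_identical(got$shared,
                     sort(intersect(intersect(brute, expr[[1]]), expr[[2]])))
  }
})

test_that("hypothesis I requires concordant significant regulators in every context", {
  # enumerate sign patterns for regulator X across two contexts
  for (sa in c(-1, 0, 1)) {
    for (sb in c(-1, 0, 1)) {
      cr <- list(A = make_context(c(X = sa * 2, Y = 0, FASL = -2)),
                 B = make_context(c(X = sb * 2, Y = 0, FASL = -2)))
      h <- hypothesis1("FASL", reg3, cr)
      if (sa != 0 && sa == sb) {
        expect_identical(h$status, "explained")
        expect_identical(h$explained_by$tf, "X")
        expect_identical(h$explained_by$direction, if (sa < 0) "down" else "up")
      } else {
        expect_identical(h$status, "failed")
      }
    }
  }
})

test_that("mutual differential TFs are the per-direction intersections", {
  cr <- list(A = make_context(c(T1 = -2, T2 = -2, T3 = 2, T4 = 0)),
             B = make_context(c(T1 = -2, T2 = 0, T3 = 2, T4 = -2)))
  m <- mutual_differential_tfs(c("T1", "T2", "T3", "T4"), cr)
  expect_identical(m$down, "T1")
  expect_identical(m$up, "T3")

  set.seed(15)
  for (i in 1:5) {
    tfs <- sprintf("T%02d", 1:10)
    sa <- sample(c(-2, 0, 2), 10, TRUE)
    sb <- sample(c(-2, 0, 2), 10, TRUE)
    cr_r <- list(A = make_context(setNames(sa, tfs)), B = make_context(setNames(sb, tfs)))
    got <- mutual_differential_tfs(tfs, cr_r)
    expect_identical(got$down, sort(tfs[sa == -2 & sb == -2]))
    expect_identical(got$up, sort(tfs[sa == 2 & sb == 2]))
  }
})

test_that("PPI linking keeps physical edges to regulators at or above min score", {
  ppi <- data.frame(protein_a = c("R3", "R3", "R3", "Q"),
                    protein_b = c("E1", "E2", "E3", "E1"),
                    physical = c(TRUE, FALSE, TRUE, TRUE),
                    score = c(900, 950, 150, 800), stringsAsFactors = FALSE)
  links <- ppi_link(c("R3", "Q"), c("E1", "E2", "E3"), ppi)
  expect_identical(links$R3$partner, c("E1", "E3"))   # physical only
  expect_identical(links$Q$partner, "E1")
  links2 <- ppi_link("R3", c("E1", "E2", "E3"), ppi, min_score = 500)
  expect_identical(links2$R3$partner, "E1")
  # undirected: reversed edge direction is equivalent
  rev <- ppi; rev[c("protein_a", "protein_b")] <- ppi[c("protein_b", "protein_a")]
  expect_identical(ppi_link(c("R3", "Q"), c("E1", "E2", "E3"), rev), links)
  # candidate without partners is dropped
  expect_false("Z" %in% names(ppi_link("Z", "E1", ppi)))
})

test_that("hypothesis II ranks the planted co-TF and reacts to evidence changes", {
  reg <- data.frame(tf = c("E1", "E2", "R3", "R4"),
                    target = c("FASL", "FASL", "G1", "G2"),
                    confidence = "C", sign = 0L, stringsAsFactors = FALSE)
  ppi <- data.frame(protein_a = "R3", protein_b = "E1", physical = TRUE,
                    score = 900, stringsAsFactors = FALSE)
  de <- c(E1 = 0, E2 = 0, R3 = -2, R4 = -2, FASL = -2)
  cr <- list(A = make_context(de, openness = c(R3 = "closed", E1 = "unchanged")),
             B = make_context(de, openness = c(R3 = "closed", E1 = "unchanged")))

  cand <- hypothesis2("FASL", reg, ppi, cr, motif_supported_partners = "E1")
  expect_identical(cand$cotf[1], "R3")
  expect_identical(cand$best_partner[1], "E1")
  expect_identical(cand$rank_score[1], 6L)
  expect_false("R4" %in% cand$cotf)          # no physical edge

  # deleting the edge removes the candidate
  no_edge <- ppi[0, ]
  expect_identical(nrow(hypothesis2("FASL", reg, no_edge, cr)), 0L)

  # partner also significantly down: retained, but with a lower rank score
  de2 <- de; de2["E1"] <- -2
  cr2 <- list(A = make_context(de2, openness = c(R3 = "closed", E1 = "unchanged")),
              B = make_context(de2, openness = c(R3 = "closed", E1 = "unchanged")))
  cand2 <- hypothesis2("FASL", reg, ppi, cr2, motif_supported_partners = "E1")
  expect_true("R3" %in% cand2$cotf)
  expect_false(cand2$partner_expression_unchanged[cand2$cotf == "R3"])
  expect_lt(cand2$rank_score[cand2$cotf == "R3"], 6L)

  # deterministic tie-break ends in lexicographic co-TF order
  ppi3 <- rbind(ppi, data.frame(protein_a = "A9", protein_b = "E1",
                                physical = TRUE, score = 900))
  reg3b <- rbind(reg, data.frame(tf = "A9", target = "G3", confidence = "C", sign = 0L))
  de3 <- c(de, A9 = -2)
  cr3 <- list(A = make_context(de3, openness = c(R3 = "closed", A9 = "closed", E1 = "unchanged")),
              B = make_context(de3, openness = c(R3 = "closed", A9 = "closed", E1 = "unchanged")))
  cand3 <- hypothesis2("FASL", reg3b, ppi3, cr3, motif_supported_partners = "E1")
  expect_identical(cand3$cotf, c("A9", "R3"))
})

test_that("removing a context can only grow or preserve the mutual sets", {
  set.seed(16)
  tfs <- sprintf("T%02d", 1:15)
  sa <- setNames(sample(c(-2, 0, 2), 15, TRUE), tfs)
  sb <- setNames(sample(c(-2, 0, 2), 15, TRUE), tfs)
  both <- mutual_differential_tfs(tfs, list(A = make_context(sa), B = make_context(sb)))
  only_a <- mutual_differential_tfs(tfs, list(A = make_context(sa)))
  expect_true(all(both$down %in% only_a$down))
  expect_true(all(both$up %in% only_a$up))
})
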