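test_that("the genome-wide filter is strict at the boundary and order-preserving", {
  rec <- makeRecords(c("rs1", "rs2", "rs3"), beta = rep(0.1, 3),
                     se = rep(0.01, 3), pval = c(4.9e-8, 5e-8, 1e-10))
  kept <- filterGenomeWide(rec, 5e-8)
  expect_equal(kept$rsid, c("rs1", "rs3"))       # 5e-8 itself is excluded

  allSig <- makeRecords(paste0("rs", 1:5), rep(0.1, 5), rep(0.01, 5),
                        pval = rep(1e-9, 5))
  expect_equal(filterGenomeWide(allSig), allSig, ignore_attr = TRUE)

  set.seed(3)
  mixed <- makeRecords(paste0("rs", 1:10), rep(0.1, 10), rep(0.01, 10),
                       pval = 10^runif(10, -10, -6))
  expect_equal(nrow(filterGenomeWide(mixed)), sum(mixed$pval < 5e-8))
  expect_error(filterGenomeWide(mixed, 1e-30), "1e-30")
})

test_that("greedy clumping matches a brute-force oracle on a clique-and-pair fixture", {
  # 8 SNPs: rs1-rs2-rs3 a mutual clique at r2 = 0.6, rs5/rs6 a pair at 0.4
  ids <- paste0("rs", 1:8)
  rec <- makeRecords(ids, rep(0.1, 8), rep(0.01, 8),
                     pval = c(1e-9, 1e-11, 1e-10, 1e-8, 1e-12, 1e-9, 1e-8, 1e-8))
  ld <- data.frame(
    rsid_a = c("rs1", "rs1", "rs2", "rs5"),
    rsid_b = c("rs2", "rs3", "rs3", "rs6"),
    r2 = c(0.6, 0.6, 0.6, 0.4))
  m <- matrix(0, 8, 8, dimnames = list(ids, ids))
  for (k in seq_len(nrow(ld))) {
    m[ld$rsid_a[k], ld$rsid_b[k]] <- ld$r2[k]
    m[ld$rsid_b[k], ld$rsid_a[k]] <- ld$r2[k]
  }
  got <- ldClump(rec, ld, 0.001)
  expect_equal(sort(got$rsid), greedyClumpOracle(rec, m, 0.001))
  # clique keeps exactly its lowest-p member; pair keeps its lowest-p member
  expect_true("rs2" %in% got$rsid && !any(c("rs1", "rs3") %in% got$rsid))
  expect_true("rs5" %in% got$rsid && !"rs6" %in% got$rsid)
  expect_setequal(attr(got, "clumped"), c("rs1", "rs3", "rs6"))

  # two SNPs at r2 = 0.5: only the smaller p survives
  two <- makeRecords(c("rsA", "rsB"), c(0.1, 0.1), c(0.01, 0.01),
                     pval = c(1e-9, 1e-8))
  ld2 <- data.frame(rsid_a = "rsA", rsid_b = "rsB", r2 = 0.5)
  expect_equal(ldClump(two, ld2, 0.001)$rsid, "rsA")

  # empty LD table: identity
  expect_equal(ldClump(rec, ld[0, ], 0.001)$rsid, rec$rsid)
})

test_that("clumping is row-order invariant for distinct p-values and every retained pair is unlinked", {
  set.seed(9)
  ids <- paste0("rs", 1:12)
  rec <- makeRecords(ids, rep(0.1, 12), rep(0.01, 12),
                     pval = 10^runif(12, -12, -8))
  pairs <- t(combn(ids, 2))
  ld <- data.frame(rsid_a = pairs[, 1], rsid_b = pairs[, 2],
                   r2 = ifelse(runif(nrow(pairs)) < 0.25,
                               runif(nrow(pairs), 0.1, 0.9), 0))
  a <- ldClump(rec, ld, 0.001)
  b <- ldClump(rec[sample(12), ], ld, 0.001)
  expect_setequal(a$rsid, b$rsid)
  # directly assertable invariant: retained pairs all have r2 <= threshold
  for (i in seq_len(nrow(a))) for (k in seq_len(nrow(a))) {
    if (i >= k) next
    hit <- ld[(ld$rsid_a == a$rsid[i] & ld$rsid_b == a$rsid[k]) |
              (ld$rsid_b == a$rsid[i] & ld$rsid_a == a$rsid[k]), "r2"]
    expect_true(all(hit <= 0.001))
  }
})

test_that("proxy substitution picks the best acceptable proxy and reports drops", {
  req <- c("rs1", "rs2", "rs3")
  # all present: identity mapping
  idm <- substituteProxies(req, req, NULL)
  expect_equal(idm$mapping$used, req)
  expect_length(idm$dropped, 0L)

  proxies <- data.frame(
    rsid = c("rs2", "rs2", "rs3"),
    proxy_rsid = c("rp85", "rp95", "rp70"),
    r2 = c(0.85, 0.95, 0.7))
  avail <- c("rs1", "rp85", "rp95", "rp70")
  got <- suppressMessages(substituteProxies(req, avail, proxies, 0.8))
  expect_equal(got$mapping$used[got$mapping$requested == "rs2"], "rp95")
  # only proxy at r2 = 0.7 is below the > 0.8 rule: dropped, not substituted
  expect_equal(got$dropped, "rs3")
  expect_false("rs3" %in% got$mapping$requested)
})

test_that("confounder exclusion removes exactly the blacklisted SNPs and is idempotent", {
  rec <- makeRecords(paste0("rs", 1:6), rep(0.1, 6), rep(0.01, 6))
  expect_equal(excludeConfounders(rec, character()), rec, ignore_attr = TRUE)
  bl <- c("rs2", "rs5", "rs999")
  once <- suppressMessages(excludeConfounders(rec, bl))
  expect_equal(nrow(once), 4L)
  expect_equal(attr(once, "removed"), c("rs2", "rs5"))
  twice <- excludeConfounders(once, bl)
  expect_equal(twice$rsid, once$rsid)
})

test_that("instrument strength matches hand arithmetic", {
  rec <- makeRecords("rs1", beta = 0.1, se = 0.01)
  expect_equal(instrumentStrength(rec, 1e5)@perSnpF, 100)
  rec$beta <- 0
  expect_equal(instrumentStrength(rec, 1e5)@perSnpF, 0)

  three <- makeRecords(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.08, 0.12),
                       se = c(0.01, 0.012, 0.009), eaf = c(0.2, 0.3, 0.4))
  st <- instrumentStrength(three, nExposure = 187365, k = 3)
  r2Hand <- 2 * 0.2 * 0.8 * 0.1^2 + 2 * 0.3 * 0.7 * 0.08^2 +
    2 * 0.4 * 0.6 * 0.12^2
  expect_equal(st@r2Explained, r2Hand)
  expect_equal(st@aggregateF, ((187365 - 3 - 1) / 3) * r2Hand / (1 - r2Hand))
  expect_equal(st@meanF, mean(st@perSnpF))

  three$eaf[2] <- NA
  st2 <- instrumentStrength(three, 187365)
  expect_true(is.na(st2@aggregateF))
  expect_length(st2@perSnpF, 3L)
})

test_that("the selection pipeline runs filter -> confounders -> clump with a conserving ledger", {
  set.seed(21)
  rec <- makeRecords(paste0("rs", 1:20), rep(0.1, 20), rep(0.01, 20),
                     pval = c(rep(1e-10, 15), rep(1e-6, 5)))
  ld <- data.frame(rsid_a = "rs1", rsid_b = "rs2", r2 = 0.9)
  cfg <- selectionConfig(blacklist = c("rs3", "rs17"))
  out <- suppressMessages(selectInstruments(rec, cfg, ld))
  ledger <- attr(out, "ledger")
  expect_equal(ledger$stage,
               c("genome_wide_filter", "confounder_exclusion", "ld_clumping"))
  # each stage's output feeds the next, counts conserve
  expect_equal(ledger$n_in[-1], ledger$n_out[-3])
  expect_equal(ledger$n_in - ledger$n_out, ledger$n_excluded)
  expect_equal(nrow(out), 20 - 5 - 1 - 1)  # p-filter 5, blacklist rs3, clump rs2
})
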