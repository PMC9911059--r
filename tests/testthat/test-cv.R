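mkTable <- function(nCultivars = 10, envs = c("HEL2020", "MOS2020",
                                              "HEL2021"),
                    traits = c("t1", "t2"), seed = 1) {
    set.seed(seed)
    ids <- sprintf("g%02d", seq_len(nCultivars))
    gridTable(ids, envs, traits,
              rnorm(nCultivars * length(envs) * length(traits)))
}

test_that("70% schemes mask round(0.7 n) cultivars, same across traits", {
    tbl <- mkTable()
    plan <- makeCVPlan("M1Sp", tbl, "HEL2021", nRepeats = 4, seed = 11)
    for (fold in cvFolds(plan)) {
        # 7 of 10 cultivars, every trait, target environment only
        expect_setequal(unique(fold$environment), "HEL2021")
        perTrait <- split(fold$cultivar, fold$trait)
        expect_true(all(lengths(perTrait) == 7L))
        expect_identical(sort(unique(perTrait$t1)),
                         sort(unique(perTrait$t2)))
    }
})

test_that("M4Mp* masks independently per trait", {
    tbl <- mkTable(nCultivars = 10, traits = sprintf("t%d", 1:7))
    plan <- makeCVPlan("M4Mp*", tbl, "HEL2021", nRepeats = 5, seed = 3)
    anyDiffer <- FALSE
    for (fold in cvFolds(plan)) {
        perTrait <- lapply(split(fold$cultivar, fold$trait), unique)
        expect_true(all(lengths(perTrait) == 7L))
        if (length(unique(vapply(perTrait,
                                 function(x) paste(sort(x),
                                                   collapse = ","),
                                 ""))) > 1L)
            anyDiffer <- TRUE
    }
    # with 7 independent 7-of-10 samples some trait masks must differ
    expect_true(anyDiffer)
    # and some cultivar is masked for one trait but observed for another
    fold <- cvFolds(plan)[[1]]
    perTrait <- lapply(split(fold$cultivar, fold$trait), unique)
    un <- unique(unlist(perTrait))
    expect_true(any(vapply(un, function(cv)
        !all(vapply(perTrait, function(s) cv %in% s, TRUE)), TRUE)))
})

test_that("whole-environment schemes mask every target cell once", {
    tbl <- mkTable()
    plan <- makeCVPlan("M1Sa", tbl, c("HEL2021"), fraction = 1,
                       seed = 5)
    expect_length(cvFolds(plan), 1L)
    fold <- cvFolds(plan)[[1]]
    expect_equal(nrow(fold), 10 * 1 * 2)   # all cultivars x traits
    expect_error(makeCVPlan("M1Sa", tbl, "HEL2021", fraction = 0.7),
                 "fraction = 1")
    expect_error(makeCVPlan("M1Sp", tbl, "HEL2021", fraction = 1.2),
                 "fraction")
    expect_error(makeCVPlan("M9Xx", tbl, "HEL2021"), "unknown scheme")
})

test_that("fold generation is seed-deterministic", {
    tbl <- mkTable()
    p1 <- makeCVPlan("M4Mp", tbl, "HEL2021", nRepeats = 10, seed = 42)
    p2 <- makeCVPlan("M4Mp", tbl, "HEL2021", nRepeats = 10, seed = 42)
    expect_identical(cvFolds(p1), cvFolds(p2))
    p3 <- makeCVPlan("M4Mp", tbl, "HEL2021", nRepeats = 10, seed = 43)
    expect_false(identical(cvFolds(p1), cvFolds(p3)))
    # identical folds reusable across compared models: the plan is
    # model-independent data, so the same object serves both fits
    expect_equal(p1@model, "M4")
})

test_that("fold masks partition the target cells", {
    tbl <- mkTable()
    plan <- makeCVPlan("M2Sp", tbl, "HEL2021", nRepeats = 3, seed = 9,
                       traits = "t1")
    all10 <- sprintf("g%02d", 1:10)
    for (fold in cvFolds(plan)) {
        masked <- unique(fold$cultivar)
        observedSet <- setdiff(all10, masked)
        expect_length(intersect(masked, observedSet), 0L)
        expect_setequal(union(masked, observedSet), all10)
    }
})

test_that("COR and PMSE match their formula oracles", {
    expect_equal(scorePredictions(c(1, 2, 3), c(2, 4, 6)),
                 c(COR = 1, PMSE = 14 / 3))
    expect_equal(scorePredictions(c(1, 2, 3), c(3, 2, 1)),
                 c(COR = -1, PMSE = 8 / 3))
    set.seed(2)
    o <- rnorm(1000); p <- 0.4 * o + rnorm(1000)
    s <- scorePredictions(o, p)
    # two-pass textbook formulas
    corRef <- sum((o - mean(o)) * (p - mean(p))) /
        sqrt(sum((o - mean(o))^2) * sum((p - mean(p))^2))
    expect_equal(s[["COR"]], corRef, tolerance = 1e-12)
    expect_equal(s[["PMSE"]], sum((o - p)^2) / 1000, tolerance = 1e-12)
    # PMSE invariant under pair permutation
    i <- sample(1000)
    expect_equal(scorePredictions(o[i], p[i])[["PMSE"]], s[["PMSE"]])
    # degenerate predictor: COR undefined, PMSE is the (biased) variance
    expect_warning(s0 <- scorePredictions(o, rep(mean(o), 1000)),
                   "zero variance")
    expect_true(is.na(s0[["COR"]]))
    expect_equal(s0[["PMSE"]], mean((o - mean(o))^2))
})

test_that("runScheme aggregates per-fold metrics self-consistently", {
    set.seed(21)
    panel <- randomPanel(20, 50, seed = 77)
    K <- tetraKinship(panel)
    cfg <- scenarioConfig(nCultivars = 20, nSnps = 50,
                          nEnvironments = 2, nTraits = 1, model = "M1")
    sim <- simulateTrial(panel, cfg, kinship = K)
    envs <- environmentNames(sim$table)
    plan <- makeCVPlan("M1Sp", sim$table, envs[2], nRepeats = 3,
                       seed = 13)
    res <- runScheme(sim$table, K, plan,
                     settings = mcmcSettings(400, 100, 2, seed = 14),
                     rhatThreshold = Inf)
    m <- res$metrics
    expect_setequal(m$metric, c("COR", "PMSE"))
    expect_true(all(m$n_folds == 3))
    expect_true(all(m$mean[m$metric == "PMSE"] >= 0))
    expect_true(all(abs(m$mean[m$metric == "COR"]) <= 1))
    # mean/sd recomputable from the per-fold records
    pf <- res$perFold
    corRow <- m[m$metric == "COR", ]
    expect_equal(corRow$mean, mean(pf$COR), tolerance = 1e-12)
    expect_equal(corRow$sd, sd(pf$COR), tolerance = 1e-12)
    # per-fold prediction records carry scheme/fold labels
    expect_setequal(unique(res$predictions$fold), 1:3)
    expect_setequal(unique(res$predictions$scheme), "M1Sp")
})

test_that("folds with too few scoreable cells are skipped with warning", {
    set.seed(31)
    panel <- randomPanel(4, 30, seed = 31)
    K <- tetraKinship(panel)
    ids <- cultivarIds(K)
    tbl <- gridTable(ids, c("E1", "E2"), "t1", rnorm(8))
    plan <- makeCVPlan("M1Sp", tbl, "E2", fraction = 0.5, nRepeats = 2,
                       seed = 8)
    # 2 of 4 masked -> < 3 scoreable cells per fold
    expect_error(
        suppressWarnings(runScheme(tbl, K, plan,
            settings = mcmcSettings(200, 50, 1, 1),
            rhatThreshold = Inf)),
        "all folds were skipped")
    expect_warning(
        try(runScheme(tbl, K, plan,
            settings = mcmcSettings(200, 50, 1, 1),
            rhatThreshold = Inf), silent = TRUE),
        "fewer than 3")
})

test_that("phenotypic correlations recover structure and degeneracies", {
    # identical values in two environments -> correlation exactly 1
    ids <- sprintf("g%02d", 1:8)
    v <- rnorm(8)
    tbl <- gridTable(ids, c("A", "B"), "t1", c(v, v))
    pc <- phenotypicCorrelations(tbl, "B", "A")
    expect_equal(pc$t1, 1)
    # insufficient overlap -> NA
    rec <- trialRecords(tbl)
    drop <- rec$environment == "A" & rec$cultivar %in% ids[1:6]
    rec$value[drop] <- NA
    rec$observed[drop] <- FALSE
    tbl2 <- TrialTable(rec, environments = c("A", "B"), traits = "t1")
    pc2 <- phenotypicCorrelations(tbl2, "B", "A")
    expect_true(is.na(pc2$t1))
    # trait columns keep the table's trait order
    tblM <- mkTable(traits = c("<40 mm", "40-50 mm", "Starch"))
    pcM <- phenotypicCorrelations(tblM, "HEL2021")
    expect_identical(names(pcM)[-(1:2)], c("<40 mm", "40-50 mm", "Starch"))
})

test_that("near-zero generative correlation gives near-zero estimate", {
    set.seed(41)
    panel <- randomPanel(250, 60, seed = 41)
    K <- tetraKinship(panel)
    cfg <- scenarioConfig(nCultivars = 250, nSnps = 60,
                          nEnvironments = 2, nTraits = 1, model = "M2",
                          truth = list(UE = diag(c(1, 1)),
                                       sigma2 = c(1, 1)))
    sim <- simulateTrial(panel, cfg, kinship = K)
    envs <- environmentNames(sim$table)
    pc <- phenotypicCorrelations(sim$table, envs[2], envs[1])
    expect_lt(abs(pc$trait1), 0.15)
})
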