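# shared small fixture: 12 cultivars, 3 environments
fixKin <- local({
    panel <- randomPanel(12, 40, seed = 101)
    tetraKinship(panel)
})
fixLines <- cultivarIds(fixKin)

test_that("model covariances match the entry-wise distributional oracle", {
    K <- kinshipMatrix(subsetKinship(fixKin, fixLines[1:5]))
    m <- 2
    p1 <- list(sigma2_g = 1.3, sigma2_ge = 0.6, sigma2_e = 0.4)
    expect_equal(marginalCovariance("M1", K, m, p1),
                 entrywiseCovariance("M1", K, m, p1), tolerance = 1e-14)
    p2 <- list(UE = matrix(c(1, .7, .7, 1.5), 2), sigma2 = c(0.5, 1.2))
    expect_equal(marginalCovariance("M2", K, m, p2),
                 entrywiseCovariance("M2", K, m, p2), tolerance = 1e-14)
    p3 <- c(p2, list(FE = matrix(c(.8, .4, .4, .8), 2)))
    expect_equal(marginalCovariance("M3", K, m, p3),
                 entrywiseCovariance("M3", K, m, p3), tolerance = 1e-14)
    p4 <- list(Ug = matrix(c(1, .5, .5, 1), 2),
               Uge = matrix(c(.5, .1, .1, .5), 2),
               Sigma = matrix(c(.6, .2, .2, .6), 2))
    expect_equal(marginalCovariance("M4", K, m, p4),
                 entrywiseCovariance("M4", K, m, p4, t = 2),
                 tolerance = 1e-14)
})

test_that("Hadamard and Kronecker G x E structures coincide", {
    # M1 with (sigma2_g, sigma2_ge) equals M2 with the compound-
    # symmetric environmental covariance UE = sigma2_g J + sigma2_ge I
    K <- kinshipMatrix(subsetKinship(fixKin, fixLines[1:5]))
    m <- 2
    sg <- 1.1; sge <- 0.45; se <- 0.3
    C1 <- marginalCovariance("M1", K, m,
        list(sigma2_g = sg, sigma2_ge = sge, sigma2_e = se))
    C2 <- marginalCovariance("M2", K, m,
        list(UE = sg * matrix(1, m, m) + sge * diag(m),
             sigma2 = rep(se, m)))
    expect_lt(max(abs(C1 - C2)), 1e-12)
})

test_that("a constant response is predicted as that constant", {
    n <- 10
    tbl <- gridTable(fixLines[1:n], c("E1", "E2"), "tr", rep(3.7, 2 * n))
    tbl <- maskCells(tbl, data.frame(cultivar = fixLines[1:3],
                                     environment = "E2", trait = "tr"))
    fit <- fitGEModel(tbl, subsetKinship(fixKin, fixLines[1:n]), "M1",
                      settings = mcmcSettings(2000, 500, 1, seed = 2))
    expect_lt(max(abs(predictions(fit)$predictive_mean - 3.7)), 0.15)
})

test_that("clamped M2 with one environment matches the ridge/MME solve", {
    n <- 12
    K <- kinshipMatrix(fixKin)
    set.seed(5)
    y <- rnorm(n)
    tbl <- gridTable(fixLines, "E1", "tr", y)
    tbl <- maskCells(tbl, data.frame(cultivar = fixLines[1:4],
                                     environment = "E1", trait = "tr"))
    pars <- list(UE = matrix(0.5), sigma2 = 1)
    fit <- fitGEModel(tbl, fixKin, "M2",
                      settings = mcmcSettings(30000, 3000, 1, seed = 6),
                      fixedVariances = pars)
    Kj <- K; diag(Kj) <- diag(Kj) + 1e-8 * mean(diag(K))
    C <- marginalCovariance("M2", Kj, 1, pars)
    rec <- oracleRecords(tbl, fixLines, "E1", "tr")
    orc <- glsConditionalPredict(C, meanDesign(rec, "E1"), rec$value,
                                 rec$observed)
    p <- predictions(fit)
    est <- alignOracle(p, rec, which(!rec$observed), orc)
    expect_lt(sqrt(mean((p$predictive_mean - est)^2)) / sd(y), 1e-2)
})

test_that("M3 with FE clamped to ~zero reduces to M2", {
    set.seed(8)
    cfgM2 <- scenarioConfig(nCultivars = 12, nSnps = 40,
                            nEnvironments = 2, nTraits = 1, model = "M2",
                            truth = list(UE = matrix(c(1, .6, .6, 1), 2),
                                         sigma2 = c(0.5, 0.8)))
    sim <- simulateTrial(randomPanel(12, 40, seed = 101), cfgM2,
                         kinship = fixKin)
    envs <- environmentNames(sim$table)
    tt <- maskCells(sim$table, data.frame(cultivar = fixLines[1:4],
                                          environment = envs[2],
                                          trait = "trait1"))
    pars <- list(UE = matrix(c(1, .6, .6, 1), 2), sigma2 = c(0.5, 0.8))
    st <- mcmcSettings(8000, 1000, 1, seed = 3)
    f2 <- fitGEModel(tt, fixKin, "M2", settings = st,
                     fixedVariances = pars)
    f3 <- fitGEModel(tt, fixKin, "M3", settings = st,
                     fixedVariances = c(pars,
                         list(FE = diag(1e-10, 2))))
    expect_lt(max(abs(predictions(f2)$predictive_mean -
                      predictions(f3)$predictive_mean)), 0.05)
})

test_that("M4 with clamped diagonal trait covariances matches per-trait M1", {
    set.seed(9)
    n <- 12
    cfg <- scenarioConfig(nCultivars = n, nSnps = 40, nEnvironments = 2,
                          nTraits = 2, model = "M4",
                          truth = list(Ug = diag(2), Uge = diag(.4, 2),
                                       Sigma = diag(.4, 2)))
    sim <- simulateTrial(randomPanel(n, 40, seed = 101), cfg,
                         kinship = fixKin)
    envs <- environmentNames(sim$table); trs <- traitNames(sim$table)
    tt <- maskCells(sim$table,
                    expand.grid(cultivar = fixLines[1:4],
                                environment = envs[2], trait = trs,
                                stringsAsFactors = FALSE))
    st <- mcmcSettings(20000, 2000, 1, seed = 4)
    f4 <- fitGEModel(tt, fixKin, "M4", settings = st,
                     fixedVariances = list(Ug = diag(2),
                                           Uge = diag(.4, 2),
                                           Sigma = diag(.4, 2)))
    p4 <- predictions(f4)
    for (j in 1:2) {
        f1 <- fitGEModel(tt, fixKin, "M1", traits = trs[j],
                         settings = mcmcSettings(20000, 2000, 1,
                                                 seed = 4 + j),
                         fixedVariances = list(sigma2_g = 1,
                                               sigma2_ge = .4,
                                               sigma2_e = .4))
        p1 <- predictions(f1)
        pj <- p4[p4$trait == trs[j], ]
        pj <- pj[match(paste(p1$cultivar, p1$environment),
                       paste(pj$cultivar, pj$environment)), ]
        expect_lt(max(abs(pj$predictive_mean - p1$predictive_mean)), 0.08)
    }
})

test_that("M3 components jointly conserve the per-environment variance", {
    cfg <- scenarioConfig(nCultivars = 150, nSnps = 150,
                          nEnvironments = 3, nTraits = 1, model = "M3",
                          nFamilies = 15,
                          truth = list(UE = matrix(.5, 3, 3) + diag(.5, 3),
                                       sigma2 = c(.5, 1, 1.5),
                                       FE = matrix(.3, 3, 3) + diag(.2, 3)))
    panel <- simulateDosages(cfg, seed = 61)
    K <- tetraKinship(panel)
    kbar <- mean(diag(kinshipMatrix(K)))
    ratios <- sapply(1:3, function(r) {
        sim <- simulateTrial(panel, cfg, seed = 70 + r, kinship = K)
        fit <- fitGEModel(sim$table, K, "M3",
                          settings = mcmcSettings(1500, 500, 2,
                                                  seed = 80 + r),
                          rhatThreshold = Inf)
        v <- colMeans(fit@posterior$varDraws)
        # total modelled variance per env: kbar*UE_ee + FE_ee + sigma2_e
        tot <- kbar * v[c("UE[1,1]", "UE[2,2]", "UE[3,3]")] +
            v[c("FE[1,1]", "FE[2,2]", "FE[3,3]")] +
            v[sprintf("sigma2[%d]", 1:3)]
        rec <- trialRecords(sim$table)
        sampVar <- tapply(rec$value, rec$environment, var)[
            environmentNames(sim$table)]
        tot / sampVar
    })
    expect_true(all(abs(rowMeans(ratios) - 1) < 0.25))
})

test_that("single-trait and multitrait guards reject bad configurations", {
    tbl2 <- gridTable(fixLines[1:4], c("E1", "E2"), c("t1", "t2"),
                      rnorm(16))
    expect_error(fitGEModel(tbl2, fixKin, "M1"), "single-trait")
    expect_error(fitGEModel(tbl2, fixKin, "M4", traits = "t1"),
                 "at least 2 traits")
    tbl1 <- gridTable(fixLines[1:4], "E1", "t1", rnorm(4))
    expect_error(fitGEModel(tbl1, fixKin, "M1"), "2 environments")
    # M2 refuses a fully unobserved environment
    tbl <- gridTable(fixLines[1:6], c("E1", "E2"), "t1", rnorm(12))
    tbl <- maskCells(tbl, data.frame(cultivar = fixLines[1:6],
                                     environment = "E2", trait = "t1"))
    expect_error(fitGEModel(tbl, fixKin, "M2",
                            settings = mcmcSettings(100, 50, 1, 1)),
                 "cannot predict full environments")
    # unknown cultivar in the table
    bad <- gridTable(c(fixLines[1:3], "ghost"), c("E1", "E2"), "t1",
                     rnorm(8))
    expect_error(fitGEModel(bad, fixKin, "M1",
                            settings = mcmcSettings(100, 50, 1, 1)),
                 "absent")
})

test_that("whole-environment prediction uses the grand-mean convention", {
    # an unrelated cultivar (identity kinship) masked everywhere is
    # predicted at the environment/grand mean
    n <- 15
    ids <- sprintf("c%02d", 1:n)
    K <- diag(n); dimnames(K) <- list(ids, ids)
    set.seed(11)
    tbl <- gridTable(ids, c("E1", "E2"), "tr",
                     c(rnorm(n, 10), rnorm(n, 12)))
    # mask all of E2: M1 must still predict (grand mean + g)
    tbl2 <- maskCells(tbl, data.frame(cultivar = ids, environment = "E2",
                                      trait = "tr"))
    fit <- fitGEModel(tbl2, K, "M1",
                      settings = mcmcSettings(3000, 500, 1, seed = 12))
    p <- predictions(fit)
    expect_equal(nrow(p), n)
    expect_equal(mean(p$predictive_mean), 10,
                 tolerance = 3 * sd(tbl@records$value[1:n]) / sqrt(n))
})

test_that("predictive sd contracts with information", {
    set.seed(13)
    cfg <- scenarioConfig(nCultivars = 12, nSnps = 40, nEnvironments = 3,
                          nTraits = 1, model = "M1")
    sim <- simulateTrial(randomPanel(12, 40, seed = 101), cfg,
                         kinship = fixKin)
    envs <- environmentNames(sim$table)
    # cultivar 1: masked everywhere; cultivar 2: masked in env 3 only
    tt <- maskCells(sim$table, rbind(
        data.frame(cultivar = fixLines[1], environment = envs,
                   trait = "trait1"),
        data.frame(cultivar = fixLines[2], environment = envs[3],
                   trait = "trait1")))
    fit <- fitGEModel(tt, fixKin, "M1",
                      settings = mcmcSettings(3000, 500, 1, seed = 14))
    p <- predictions(fit)
    sdAll <- p$predictive_sd[p$cultivar == fixLines[1] &
                             p$environment == envs[3]]
    sdOne <- p$predictive_sd[p$cultivar == fixLines[2]]
    expect_lt(sdOne, sdAll)
    expect_equal(nrow(p), 4L)
})

test_that("record order does not affect the fit (canonical re-sort)", {
    set.seed(15)
    cfg <- scenarioConfig(nCultivars = 12, nSnps = 40, nEnvironments = 2,
                          nTraits = 1, model = "M1")
    sim <- simulateTrial(randomPanel(12, 40, seed = 101), cfg,
                         kinship = fixKin)
    envs <- environmentNames(sim$table)
    tt <- maskCells(sim$table, data.frame(cultivar = fixLines[1:3],
                                          environment = envs[2],
                                          trait = "trait1"))
    r <- trialRecords(tt)
    shuf <- TrialTable(r[sample(nrow(r)), ], environments = envs,
                       traits = "trait1")
    st <- mcmcSettings(500, 100, 1, seed = 16)
    f1 <- fitGEModel(tt, fixKin, "M1", settings = st)
    f2 <- fitGEModel(shuf, fixKin, "M1", settings = st)
    expect_identical(predictions(f1), predictions(f2))
})
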