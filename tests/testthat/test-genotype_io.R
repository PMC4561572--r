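test_that("minimal Genepop files parse: dialect detection and missing sentinel", {
  f <- withr::local_tempfile(lines = c(
    "one fly", "locA", "POP", "ind1 , 150152"))
  d <- read_genepop(f)
  expect_equal(n_individuals(d), 1L)
  expect_equal(d$loci$name, "locA")
  expect_equal(unname(c(d$a1[1, 1], d$a2[1, 1])), c(150L, 152L))

  f2 <- withr::local_tempfile(lines = c(
    "missing call", "locA", "locB", "POP", "ind1 , 000000 150150"))
  d2 <- read_genepop(f2)
  expect_true(is.na(d2$a1[1, 1]) && is.na(d2$a2[1, 1]))
  expect_equal(unname(d2$a1[1, 2]), 150L)

  # 2-digit dialect
  f3 <- withr::local_tempfile(lines = c(
    "two digit", "locA", "POP", "ind1 , 1512"))
  d3 <- read_genepop(f3)
  expect_equal(unname(c(d3$a1[1, 1], d3$a2[1, 1])), c(12L, 15L))
})

test_that("Genepop parser rejects malformed input with line numbers", {
  ragged <- withr::local_tempfile(lines = c(
    "t", "locA", "locB", "POP", "i1 , 150150 160160", "i2 , 150150"))
  expect_error(read_genepop(ragged), "line 6")
  dup <- withr::local_tempfile(lines = c(
    "t", "locA", "locA", "POP", "i1 , 150150 160160"))
  expect_error(read_genepop(dup), "duplicate locus")
  mixed <- withr::local_tempfile(lines = c(
    "t", "locA", "locB", "POP", "i1 , 150150 1616"))
  expect_error(read_genepop(mixed), "width")
})

test_that("STRUCTURE two-row and one-row tables parse, -9 is missing", {
  f <- withr::local_tempfile(lines = c(
    "fly1 7 226 -9", "fly1 7 228 -9"))
  d <- read_structure_table(f, rows_per_individual = 2)
  expect_equal(n_individuals(d), 1L)
  expect_equal(d$ind$site, "7")
  expect_equal(unname(c(d$a1[1, 1], d$a2[1, 1])), c(226L, 228L))
  expect_true(is.na(d$a1[1, 2]))

  f1 <- withr::local_tempfile(lines = "fly1 7 226 228 -9 -9")
  d1 <- read_structure_table(f1, rows_per_individual = 1)
  expect_equal(unname(d1$a1[1, ]), c(226L, NA))

  odd <- withr::local_tempfile(lines = c("a 1 2", "a 1 2", "b 1 2"))
  expect_error(read_structure_table(odd), "odd number of rows")
  txt <- withr::local_tempfile(lines = c("a 1 2x", "a 1 22"))
  expect_error(read_structure_table(txt), "non-integer")
})

test_that("write/read round-trips are identities for both formats", {
  d <- tiny_dataset()
  gp <- withr::local_tempfile()
  write_genepop(d, gp)
  d2 <- read_genepop(gp)
  expect_equal(d2$a1, d$a1)
  expect_equal(d2$a2, d$a2)
  expect_equal(d2$ind$site, d$ind$site)
  expect_equal(d2$ind$id, d$ind$id)
  expect_equal(d2$loci$name, d$loci$name)

  st <- withr::local_tempfile()
  write_structure_table(d, st)
  d3 <- read_structure_table(st, locus_names = d$loci$name)
  expect_equal(d3$a1, d$a1)
  expect_equal(d3$a2, d$a2)
  expect_equal(d3$ind$site, d$ind$site)

  # cross-format agreement on the same synthetic dataset
  sim <- simulate_study(sim_config(n_sites = 3, n_per_population = 5,
                                   n_loci = 4, seed = 71))
  gp2 <- withr::local_tempfile(); st2 <- withr::local_tempfile()
  write_genepop(sim$dataset, gp2)
  write_structure_table(sim$dataset, st2)
  dg <- read_genepop(gp2)
  ds <- read_structure_table(st2, locus_names = sim$dataset$loci$name)
  expect_equal(dg$a1, ds$a1)
  expect_equal(dg$a2, ds$a2)
  expect_equal(dg$ind$site, ds$ind$site)
  expect_equal(dg$a1, sim$dataset$a1)
})

test_that("parsers never drop individuals and the writers flag overflows", {
  sim <- simulate_study(sim_config(n_sites = 2, n_per_population = 7,
                                   n_loci = 3, seed = 72))
  gp <- withr::local_tempfile()
  write_genepop(sim$dataset, gp)
  expect_equal(n_individuals(read_genepop(gp)), n_individuals(sim$dataset))

  big <- tiny_dataset()
  big$a1[1, 1] <- 1500L; big$a2[1, 1] <- 1502L
  expect_error(write_genepop(big, withr::local_tempfile()),
               "write_structure_table")
  # empty dataset -> header-only file
  empty <- tiny_dataset()[integer(0), ]
  f <- withr::local_tempfile()
  write_genepop(empty, f)
  expect_equal(length(readLines(f)), 1L + 3L)  # title + 3 locus names
})

test_that("site table reading and geography attachment validate labels", {
  f <- withr::local_tempfile(lines = c(
    "site\tlat\tlon\tpair\tspecies",
    "north\t46.1\t-122.4\tP1\tA",
    "south\t46.1\t-122.39\tP1\tB"))
  geo <- read_site_table(f)
  expect_equal(geo$site, c("north", "south"))
  d <- tiny_dataset()
  d$ind$species <- NA_character_
  d2 <- attach_geography(d, geo)
  expect_equal(d2$ind$species, c("A", "A", "B", "B"))
  geo_bad <- geo[1, ]
  expect_error(attach_geography(d, geo_bad), "south")
  bad <- withr::local_tempfile(lines = c("site,lat", "x,1"))
  expect_error(read_site_table(bad), "lacks column")
})

test_that("the dataset container enforces its invariants", {
  expect_error(
    genotype_dataset(matrix(1L), matrix(NA_integer_),
                     data.frame(id = "i", site = "s", species = "A"),
                     data.frame(name = "l")),
    "half-missing")
  expect_error(
    genotype_dataset(matrix(-2L), matrix(3L),
                     data.frame(id = "i", site = "s", species = "A"),
                     data.frame(name = "l")),
    "positive")
  # unordered pair stored canonically
  d <- genotype_dataset(matrix(9L), matrix(4L),
                        data.frame(id = "i", site = "s", species = "A"),
                        data.frame(name = "l"))
  expect_true(d$a1[1, 1] <= d$a2[1, 1])
})
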