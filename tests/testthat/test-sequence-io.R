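test_that("validate_sequence cleans, uppercases and rejects per contract", {
  expect_equal(validate_sequence("acdEF gh")$residues, "ACDEFGH")
  expect_true(validate_sequence("acdEF gh")$accepted)

  rej <- validate_sequence("ACDXFG")
  expect_false(rej$accepted)
  expect_match(rej$reason, "X")

  for (bad in c("B", "J", "O", "U", "Z")) {
    expect_false(validate_sequence(paste0("ACDE", bad, "FG"))$accepted)
  }
  empty <- validate_sequence("  \t ")
  expect_false(empty$accepted)
  expect_match(empty$reason, "empty")
  expect_error(validate_sequence(NULL))
})

test_that("read_fasta parses header labels, sidecar manifests and skips", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">seq1|label=CML", "ACDEFGHIK",
               ">seq2|label=Control", "MNPQRST", "VWYA",
               ">seq3|label=CML", "ACDXFG"), tf)
  ds <- read_fasta(tf)
  expect_s3_class(ds, "protein_dataset")
  expect_equal(nrow(ds), 2L)
  expect_equal(class_counts(ds), c(CML = 1L, Control = 1L))
  expect_equal(ds$residues[ds$id == "seq2"], "MNPQRSTVWYA")  # wrapped body
  sk <- attr(ds, "skipped")
  expect_equal(sk$id, "seq3")

  # sidecar manifest overrides header tags
  mf <- tempfile()
  writeLines(c("seq1\tControl", "seq2\tControl"), mf)
  ds2 <- read_fasta(tf, manifest = mf)
  expect_equal(unname(class_counts(ds2)["Control"]), 2L)

  # duplicate ids are an error naming the id
  writeLines(c(">dup", "ACDE", ">dup", "ACDF"), tf)
  expect_error(read_fasta(tf), "dup")
  expect_error(read_fasta(tempfile()), "cannot read")
})

test_that("FASTA round-trip preserves ids, residues and labels", {
  ds <- protein_dataset(paste0("s", 1:5),
                        random_residues(5, 130, seed = 3),
                        c("CML", "Control", "CML", NA, "Control"))
  tf <- tempfile(fileext = ".fasta")
  write_fasta(ds, tf)
  back <- read_fasta(tf)
  expect_equal(back$id, ds$id)
  expect_equal(back$residues, ds$residues)
  expect_equal(back$label, ds$label)
})

test_that("stratified split reproduces the documented rounding exactly", {
  # balanced corpus of 1,600 at 70/15/15 -> 1,120/240/240 with 560+560 train
  ds <- protein_dataset(
    paste0("p", 1:1600),
    c(random_residues(800, 60, seed = 1), random_residues(800, 60, seed = 2)),
    rep(c("CML", "Control"), each = 800))
  sp <- stratified_split(ds, split_spec(seed = 42))
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 1120L, validation = 240L, test = 240L))
  expect_equal(class_counts(sp$train), c(CML = 560L, Control = 560L))
  expect_equal(class_counts(sp$validation), c(CML = 120L, Control = 120L))
  expect_equal(class_counts(sp$test), c(CML = 120L, Control = 120L))
})

test_that("split floor-remainder rule, partition property and determinism", {
  # 10 sequences of one class: floor gives 7/1/1, remainder -> train => 8/1/1
  ds <- protein_dataset(paste0("x", 1:10), random_residues(10, 40),
                        rep("CML", 10))
  sp <- stratified_split(ds, split_spec(seed = 7, stratified = TRUE))
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 8L, validation = 1L, test = 1L))

  # partition: union = input, pairwise disjoint
  all_ids <- unlist(lapply(sp, function(d) d$id))
  expect_setequal(all_ids, ds$id)
  expect_equal(anyDuplicated(all_ids), 0L)

  # same seed twice -> identical membership
  sp2 <- stratified_split(ds, split_spec(seed = 7))
  expect_identical(lapply(sp, function(d) d$id), lapply(sp2, function(d) d$id))

  # error cases
  expect_error(stratified_split(protein_dataset("a", "ACDE", "CML"),
                                split_spec()), "at least")
  expect_error(split_spec(fractions = c(0.5, 0.3, 0.3)), "sum to 1")
  unl <- protein_dataset("u1", "ACDE")
  expect_error(stratified_split(unl, split_spec()), "labeled")
})

test_that("write_split emits three FASTA files plus a JSON manifest", {
  ds <- protein_dataset(paste0("w", 1:20), random_residues(20, 30),
                        rep(c("CML", "Control"), 10))
  sp <- stratified_split(ds, split_spec(seed = 1))
  prefix <- tempfile()
  write_split(sp, prefix)
  man <- jsonlite::read_json(paste0(prefix, "_splits.json"),
                             simplifyVector = TRUE)
  expect_setequal(names(man), c("train", "validation", "test"))
  expect_equal(sort(unname(unlist(man))), sort(ds$id))
  got <- read_fasta(paste0(prefix, "_train.fasta"))
  expect_equal(got$id, sp$train$id)
})

test_that("protein_dataset enforces its invariants", {
  expect_error(protein_dataset(c("a", "a"), c("ACD", "ACE")), "duplicate")
  expect_error(protein_dataset("a", "ACDX"), "invalid residues")
  expect_error(protein_dataset(c("a", "b"), "ACD"), "same length")
})
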