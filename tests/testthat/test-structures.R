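test_that("a minimal C-alpha PDB parses into a complete StructureModel", {
  p <- write_pdb_fixture(c(pdb_atom_line(1, 0, 0, 0, 1),
                           pdb_atom_line(2, 3.8, 0, 0, 2),
                           pdb_atom_line(3, 7.6, 0, 0, 3)))
  m <- read_structure(p)
  expect_s3_class(m, "StructureModel")
  expect_equal(nrow(m$residues), 3)
  expect_true(all(m$residues$has_ca))
  expect_equal(m$residues$x, c(0, 3.8, 7.6))
})

test_that("residues lacking a C-alpha are kept but flagged coordinate-absent", {
  p <- write_pdb_fixture(c(
    pdb_atom_line(1, 0, 0, 0, 1),
    pdb_atom_line(2, 1, 1, 1, 2, name = " CB "),  # residue 2 has no CA
    pdb_atom_line(3, 7.6, 0, 0, 3)))
  m <- read_structure(p)
  expect_equal(nrow(m$residues), 3)
  expect_equal(m$residues$has_ca, c(TRUE, FALSE, TRUE))
  expect_true(is.na(m$residues$x[2]))
  expect_equal(m$residues$x[c(1, 3)], c(0, 7.6))
})

test_that("the first-listed alternate location of the C-alpha wins", {
  p <- write_pdb_fixture(c(pdb_atom_line(1, 1, 0, 0, 1, altloc = "A"),
                           pdb_atom_line(2, 9, 0, 0, 1, altloc = "B"),
                           pdb_atom_line(3, 5, 0, 0, 2)))
  m <- read_structure(p)
  expect_equal(nrow(m$residues), 2)
  expect_equal(m$residues$x[1], 1)
})

test_that("chain selection errors name the available chains", {
  p <- write_pdb_fixture(c(pdb_atom_line(1, 0, 0, 0, 1, chain = "A"),
                           pdb_atom_line(2, 5, 0, 0, 1, chain = "B")))
  expect_error(read_structure(p, chains = "Z"), "available chains: A,B")
  m <- read_structure(p, chains = "B")
  expect_equal(unique(m$residues$chain), "B")
})

test_that("modified residues translate to the parent amino acid", {
  p <- write_pdb_fixture(c(pdb_atom_line(1, 0, 0, 0, 1, resid = "MSE"),
                           pdb_atom_line(2, 3.8, 0, 0, 2)))
  m <- read_structure(p)
  expect_equal(m$residues$aa, c("M", "A"))
})

test_that("PDB round trip preserves residue keys and coordinates to 3 decimals", {
  spec <- synthetic_spec(n_residues = 40, seed = 11)
  m <- make_structure(spec)
  out <- tempfile(fileext = ".pdb")
  write_structure(m, out)
  m2 <- read_structure(out)
  expect_equal(m2$residues$chain, m$residues$chain)
  expect_equal(m2$residues$resno, m$residues$resno)
  expect_equal(m2$residues$x, round(m$residues$x, 3))
  expect_equal(m2$residues$z, round(m$residues$z, 3))
})

aa_model <- function(aa, has_ca = TRUE, chain = "A") {
  n <- length(aa)
  has_ca <- rep_len(has_ca, n)
  structure_model("toy", data.frame(
    chain = chain, resno = seq_len(n), ins = "", resid = "ALA", aa = aa,
    x = ifelse(has_ca, 3.8 * seq_len(n), NA), y = 0, z = 0,
    stringsAsFactors = FALSE))
}

test_that("identity alignment maps every position and leaves nothing unmapped", {
  seqs <- strsplit("ACDEFGHIKL", "")[[1]]
  m <- aa_model(seqs)
  rmap <- build_residue_map("ACDEFGHIKL", c("ACDEFGHIKL", "ACDEFGHIKL"),
                            m, "A")
  expect_equal(nrow(rmap$entries), 10)
  expect_equal(rmap$entries$human_pos, 1:10)
  expect_equal(rmap$entries$resno, 1:10)
  expect_equal(nrow(rmap$unmapped), 0)
  expect_true(all(rmap$entries$match))
})

test_that("a gap in the structure row shifts the mapping and records the gap", {
  # human positions 4-5 (E, F) have no structural counterpart
  m <- aa_model(strsplit("ACDGHIKL", "")[[1]])
  rmap <- build_residue_map("ACDEFGHIKL", c("ACDEFGHIKL", "ACD--GHIKL"),
                            m, "A")
  expect_equal(rmap$unmapped$human_pos, c(4, 5))
  expect_equal(unique(rmap$unmapped$reason), "gap")
  six_on <- rmap$entries[rmap$entries$human_pos >= 6, ]
  expect_equal(six_on$resno, 4:8)  # structure numbering lags by 2
})

test_that("unresolved and substituted residues are handled distinctly", {
  m <- aa_model(strsplit("ACDWF", "")[[1]], has_ca = c(TRUE, TRUE, FALSE,
                                                       TRUE, TRUE))
  rmap <- build_residue_map("ACDEF", c("ACDEF", "ACDWF"), m, "A")
  # position 3 aligned to a residue without a C-alpha
  expect_equal(rmap$unmapped$human_pos, 3)
  expect_equal(rmap$unmapped$reason, "unresolved")
  # position 4 is an E->W substitution between orthologs: mapped, flagged
  e4 <- rmap$entries[rmap$entries$human_pos == 4, ]
  expect_false(e4$match)
  expect_equal(e4$struct_aa, "W")
  # accounting: entries + unmapped cover the full sequence
  expect_equal(nrow(rmap$entries) + nrow(rmap$unmapped), 5)
})

test_that("inconsistent alignments fail with the first offending column", {
  m <- aa_model(strsplit("ACDEF", "")[[1]])
  expect_error(build_residue_map("ACDEF", c("ACDEG", "ACDEF"), m, "A"),
               "row 1.*column: 5")
  expect_error(build_residue_map("ACDEF", c("ACDEF", "ACDEG"), m, "A"),
               "row 2.*column: 5")
  expect_error(build_residue_map("ACDEF", c("ACDEF", "ACDE"), m, "A"),
               "differ in length")
})

test_that("mapped positions round-trip through the residue map table", {
  m <- aa_model(strsplit("ACDGHIKL", "")[[1]])
  rmap <- build_residue_map("ACDEFGHIKL", c("ACDEFGHIKL", "ACD--GHIKL"),
                            m, "A")
  tab <- as.data.frame(rmap)
  expect_equal(tab$human_pos, 1:10)
  mapped <- tab[tab$status == "mapped", ]
  back <- rmap$entries$human_pos[match(mapped$struct_resnum,
                                       paste0(rmap$entries$resno,
                                              rmap$entries$ins))]
  expect_equal(back, mapped$human_pos)
  out <- tempfile(fileext = ".tsv")
  write_residue_map(rmap, out)
  expect_equal(nrow(read.delim(out)), 10)
})

test_that("variants collapse to unique sites and unmapped ones are reported", {
  m <- aa_model(strsplit("ACDEFHIKL", "")[[1]])
  rmap <- build_residue_map("ACDEFGHIKL", c("ACDEFGHIKL", "ACDEF-HIKL"),
                            m, "A")
  v <- variant_table(c(5, 5, 9), c("F", "F", "K"), c("A", "S", "R"),
                     c("MH", "MH", "CCD"))
  res <- map_variants(v, rmap)
  expect_equal(nrow(res$sites$sites), 2)  # positions 5 and 9
  expect_equal(nrow(res$mapped), 3)

  vg <- variant_table(6, "G", "D", "RRD")
  res2 <- map_variants(vg, rmap)
  expect_equal(res2$unmapped$reason, "gap")
  expect_equal(nrow(res2$mapped), 0)
})

test_that("variants whose reference residue contradicts the sequence are rejected", {
  m <- aa_model(strsplit("ACDEF", "")[[1]])
  rmap <- build_residue_map("ACDEF", c("ACDEF", "ACDEF"), m, "A")
  expect_error(map_variants(variant_table(3, "W", "R", "MH"), rmap),
               "p\\.W3R.*sequence has D")
  expect_error(map_variants(variant_table(99, "A", "R", "MH"), rmap),
               "outside")
})
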