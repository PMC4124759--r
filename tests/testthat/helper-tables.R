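# The 5-protein x 6-feature worked example and its reference correlation /
# weighted tables, used as ground truth across the suite.

table3_fixture_path <- function() {
  system.file("extdata", "table3_ipr.tsv", package = "ipr2go")
}

table3_matrix <- function() {
  build_matrix(read_annotations(table3_fixture_path(), "IPR"))
}

ipr_names <- paste0("IPR", 1:6)
protein_names <- paste0("Protein", 1:5)

# reference pairwise phi correlations for the worked example (4 d.p.)
table4_expected <- matrix(c(
   1.0000,  0.4082, 0.1667, -0.6667,  0.6124,  0.1667,
   0.4082,  1.0000, 0.4082,  0.4082,  0.2500, -0.6124,
   0.1667,  0.4082, 1.0000,  0.1667, -0.4082,  0.1667,
  -0.6667,  0.4082, 0.1667,  1.0000, -0.4082, -0.6667,
   0.6124,  0.2500, -0.4082, -0.4082, 1.0000, -0.4082,
   0.1667, -0.6124, 0.1667, -0.6667, -0.4082,  1.0000
), 6, 6, byrow = TRUE, dimnames = list(ipr_names, ipr_names))

# reference weighted re-encoding (4 d.p.). The reference table mixes rounding
# policies in its last digit, so comparisons allow one unit in the 4th
# decimal place.
table5_expected <- matrix(c(
  0.5251, 0.2076,  0.1462,  0.1462,  0.1376, -0.1628,
  0.2008, 0.1295, -0.2501,  0.3750,  0.1697,  0.3750,
  0.1389, 0.3934,  0.0889, -0.1334,  0.0122,  0.5000,
  0.2633, 0.0725,  0.2633,  0.2500,  0.2500, -0.0991,
  0.7990, 0.2500, -0.0633,  0.2500, -0.1724, -0.0633
), 5, 6, byrow = TRUE, dimnames = list(protein_names, ipr_names))

tol_4dp <- 2.5e-4  # one unit in the 4th decimal
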