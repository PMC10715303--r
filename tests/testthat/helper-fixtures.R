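# Shared fixtures: packaged tables and the synthetic paralog pair set.

fixture_path <- function(name) {
  system.file("extdata", name, package = "setphen", mustWork = TRUE)
}

table1_variants <- function() read_variant_table(fixture_path("table1_variants.tsv"))

table1_raw <- function() read_tsv_table(fixture_path("table1_variants.tsv"))

table2_scores <- function() read_score_panel(fixture_path("table2_scores.tsv"))

clinvar_counts <- function(gene) {
  tab <- read_tsv_table(fixture_path("clinvar_class_counts.tsv"))
  tab <- tab[tab$gene == gene, ]
  stats::setNames(tab$count, tab$clinical_class)
}

# The 20 KMT2D -> KMT2C position pairs implied by the paralog-annotation
# column (constant offset 626). The target residue at the D5489E-equivalent
# position is glutamate (the already-substituted exclusion case).
table1_pairs <- function() {
  raw <- table1_raw()
  d <- raw[raw$gene == "KMT2D", ]
  src <- lapply(d$protein, parse_protein_change)
  tgt_pos <- as.integer(gsub("[^0-9]", "", d$paralog_annotation))
  tgt_res <- substr(d$paralog_annotation, 1, 1)
  tgt_res[d$variant == "D5489E"] <- "E"
  data.frame(source_pos = vapply(src, `[[`, integer(1), "position"),
             target_pos = tgt_pos,
             source_res = vapply(src, `[[`, character(1), "ref_aa"),
             target_res = tgt_res,
             alt = vapply(src, `[[`, character(1), "alt_aa"),
             source_variant = d$variant,
             annotation = d$paralog_annotation,
             stringsAsFactors = FALSE)
}

# small structure: three residues on a line, 5 A apart, CA+CB
toy_structure <- function(aa = c("A", "L", "K")) {
  n <- length(aa)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(res_index = i, name = c("CA", "CB"), element = "C",
               x = c(5 * (i - 1), 5 * (i - 1)), y = c(0, 1.5), z = 0,
               o = 1, b = 0, stringsAsFactors = FALSE)
  }))
  setphen:::new_structure(
    data.frame(chain = "A", resno = seq_len(n), aa = aa,
               stringsAsFactors = FALSE), atoms)
}

apply_rigid <- function(structure, R, t) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  structure$atoms$x <- xyz[, 1]; structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}
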