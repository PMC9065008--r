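# Small programmatic fixtures shared across tests.

# a hand-written occurrence table with known quirks
toy_occurrences <- function() {
  occurrence_table(data.frame(
    occurrence_id = as.character(1:5),
    species_name = c("Acropora alpha", "Acropora alpha", "Porites beta",
                     "Montipora cf. gamma", "Favia delta"),
    family = c("Acroporidae", "Acroporidae", "Poritidae",
               "Acroporidae", "Mussidae"),
    min_ma = c(2.58, 3.6, 0.5, 1.8, 5.33),
    max_ma = c(5.33, 5.33, 2.58, 2.58, 11.63),
    environment = c("reef", "reef", "reef", "lagoon", "reef"),
    lng = c(120, 150, -60, 45, 170),
    lat = c(-5, 10, 15, 0, 8),
    site_id = c("s1", "s2", "s3", "s1", "s2"),
    qualifier = c("none", "none", "none", "cf", "none"),
    accepted = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    extant = FALSE,
    stringsAsFactors = FALSE), provenance = "toy")
}

# a small simulated clade with occurrences, reused by several suites
toy_clade <- function(seed = 3) {
  h <- simulate_bd(sim_params(18, 3, 0.4, 0.2, seed = seed))
  occ <- simulate_preservation(h, pres_hpp(1.5), seed = seed + 100)
  list(history = h, occ = occ)
}

write_pbdb_fixture <- function(path, rows = 3L) {
  df <- data.frame(
    occurrence_no = seq_len(rows),
    accepted_name = sprintf("Genus species%d", seq_len(rows)),
    genus = rep("Genus", rows), family = rep("Familyidae", rows),
    min_ma = seq_len(rows), max_ma = seq_len(rows) + 1,
    environment = rep("reef", rows), lng = rep(10, rows),
    lat = rep(2, rows), collection_no = rep(1, rows),
    primary_reso = rep("", rows), flags = rep("A", rows))
  utils::write.csv(df, path, row.names = FALSE)
  path
}
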