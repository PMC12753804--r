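#!/usr/bin/env Rscript
# Maps the packaged XPD disease-mutation catalog onto the persistent
# contact sets of the on-path states and classifies each site:
# class A (DNA-binding, direct translocation impact), class B (nucleotide
# binding or RecA1-RecA2 interface), class C (distal). Disagreements with
# the literature annotation are surfaced in the report.

suppressPackageStartupMessages(library(helimsm))
dir.create("results", showWarnings = FALSE)

fx <- build_xpd_fixture()
f <- fx$fixture
traj <- emit_trajectory(rep(f$on_path, each = 200), f, sigma = 0.2, seed = 6L)
tab <- persistence_table(detect_contacts(traj, fx$topology),
                         rep(f$on_path, each = 200))

lig <- grepl("^L:", tab$res_a) | grepl("^L:", tab$res_b)
atp <- tab[lig & tab$persistent, ]
atp_res <- unique(helimsm:::contact_residues(
  ifelse(grepl("^P:", atp$res_a), atp$res_a, atp$res_b)))
ifc <- interface_filter(tab[tab$persistent, ], "RecA1", "RecA2",
                        topology = fx$topology)
ifc_res <- unique(helimsm:::contact_residues(c(ifc$res_a, ifc$res_b)))

catalog <- build_catalog()
report <- mutation_report(catalog, tab, atp_res, ifc_res, fx$topology)
write.csv(report, "results/xpd_mutation_report.csv", row.names = FALSE)
print(report[, c("position", "wild_type", "substitutions", "phenotype",
                 "class", "annotated_class", "agrees")])
cat(sprintf("\nclass counts: %s; %d/%d agree with the literature annotation\n",
            paste(sprintf("%s=%d", names(table(report$class)),
                          table(report$class)), collapse = " "),
            sum(report$agrees), nrow(report)))
cat("wrote results/xpd_mutation_report.csv\n")
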