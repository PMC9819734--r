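#!/usr/bin/env Rscript
# Load the two bundled inputs — the OSHA cancer-mortality calibration table
# and the two-factory chrysotile job-exposure matrix — and check their
# internal consistency before anything downstream uses them.

library(ardrisk)

dir.create("results", showWarnings = FALSE)

osha <- load_osha_table()
cat(sprintf("calibration table: %d (concentration x duration) rows\n",
            nrow(osha)))

report <- validate_osha_table(osha, tol = 1.0)
print(report)
# The single expected finding: in the 20-year block at 10 f/mL the printed
# per-cancer components sum to 19,418.7 against a printed total of 13,996.7.
readr::write_csv(report$issues, "results/osha_validation.csv")

jem <- load_jem()
cat(sprintf("JEM: %d cells (%d Harare, %d Bulawayo), concentrations %g-%g f/mL\n",
            nrow(jem), sum(jem$factory == "Harare"),
            sum(jem$factory == "Bulawayo"),
            min(jem$mean_f_ml), max(jem$mean_f_ml)))
readr::write_csv(tibble::as_tibble(jem), "results/jem.csv", na = "")
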