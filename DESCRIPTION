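Package: spikemotifs
Title: Inference of Cerebellar Microcircuit Motifs from Paired Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring functional microcircuit motifs from paired
    in vivo spike-train recordings of cerebellar molecular layer interneurons
    (INs) and Purkinje cells (PCs). Implements baseline-normalized
    cross-correlograms with block-shuffle surrogate nulls and per-bin
    Z-scores, cumulative-sum net-spike-change statistics, a shuffled
    inter-spike-interval test for triggered spikes, stimulus-locked PSTH and
    first-spike-latency analysis with fast/delayed response decomposition,
    motif classification (IN-PC inhibition, IN-IN inhibition and synchrony,
    climbing-fiber driven IN excitation/inhibition, gap-junction coupling),
    soma-geometry statistics, and a ground-truth conditional-intensity
    point-process simulator for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
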