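Package: pulsegen
Title: Quantifying KNDy-to-GnRH Dendron Signalling from Imaging and Photometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the three measurement problems that arise when
    studying how arcuate KNDy neurons drive gonadotropin-releasing hormone (GnRH)
    neuron dendrons: (1) classifying kisspeptin bouton to GnRH dendron contacts in
    expansion-microscopy image stacks as synaptic or non-synaptic from two-channel
    fluorescence overlap lengths, (2) detecting puff-evoked calcium responses in
    dendron GCaMP traces against a control-calibrated amplitude-plus-duration
    threshold, and (3) detecting KNDy synchronization events in fiber-photometry
    recordings and matching them against luteinizing hormone (LH) pulses to
    distinguish coupled from uncoupled regimes. Includes ground-truthed synthetic
    data generators for all three data types so every stage of the pipeline can be
    validated without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    pracma,
    stats,
    tiff,
    utils,
    yaml,
    zoo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
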