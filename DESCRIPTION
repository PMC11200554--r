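Package: cytovae
Title: One-Class Variational Autoencoders for Cervical Cytology
    Abnormality Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns representations of normal (NILM) cervical cells from
    Pap-smear cell-crop images with variational autoencoders (VAE,
    beta-VAE, beta-TCVAE) trained on normal samples only, and scores cell
    abnormality as the negative log-likelihood of the latent
    representation under a multivariate Gaussian estimated from
    normal-class latents.  The latent space is interpreted through
    dimension traversals, pairwise kernel-density summaries, and
    agglomerative clustering of latent posterior distributions under a
    cross-entropy-based referenced statistical distance (CRSD), a
    pseudometric on probability densities.  A synthetic cell-image
    generator with controllable nucleus morphology provides ground-truth
    fixtures so the full pipeline can be exercised without external
    cytology data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    MASS,
    png,
    EBImage,
    kernlab,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
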