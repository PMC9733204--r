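Package: stackcvae
Title: Stack-Augmented Conditional Variational Autoencoder for Molecule Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A conditional variational autoencoder for SMILES strings whose
    encoder is a stack-augmented recurrent network, together with
    policy-gradient reinforcement-learning fine-tuning of the decoder against
    synthesizability and on-/off-target binding-affinity rewards. Includes
    SMILES tokenization and corpus filtering, molecular descriptor
    conditioning (molecular weight, LogP, TPSA), deterministic mock
    affinity/synthesizability oracles for offline testing, generation metrics
    (validity, uniqueness, novelty), property-window reports, and a composite
    molecule score for top-k candidate ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
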