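Package: fdselect
Title: Selective Knowledge Sharing in Federated Distillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation framework for federated distillation in which clients
    collaborate by exchanging per-sample predictions on a shared unlabeled
    proxy set instead of model parameters. Implements a two-stage selective
    knowledge sharing mechanism: client-side selectors based on kernelized
    unconstrained least-squares importance fitting (KuLSIF) density-ratio
    estimation suppress predictions on out-of-distribution proxy samples,
    and a server-side selector based on the l1 ambiguity of ensemble
    predictions suppresses high-entropy knowledge. Includes a synthetic
    non-IID data generator, small multilayer-perceptron clients, independent
    learning, selection-free distillation and federated averaging baselines,
    selector ablations (confidence and energy scores, AUROC), threshold
    sweeps, and communication-cost accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
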