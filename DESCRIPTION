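Package: vtecea
Title: Decision-Tree Cost-Effectiveness Analysis of Thromboprophylaxis for
    Cesarean Delivery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model comparing intermittent
    pneumatic compression (IPC), low-molecular-weight heparin (LMWH), and no
    prophylaxis for venous-thromboembolism prevention in cesarean delivery,
    from a Brazilian hospital perspective. Provides the deterministic
    decision-tree rollback with pathway enumeration, incremental
    cost-effectiveness and dominance analysis, one-way (tornado), threshold,
    and scenario sensitivity analyses, probabilistic sensitivity analysis with
    beta/gamma/lognormal parameter distributions and cost-effectiveness
    acceptability curves, and a patient-level microsimulation that serves as
    an independent check of the analytic expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
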