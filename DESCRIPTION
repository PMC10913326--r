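Package: groupcog
Title: Social Drift-Diffusion and Social Reinforcement-Learning Models of
    Collective Decision-Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and likelihood-based inference for two model families
    linking individual cognition to collective dynamics: a social
    drift-diffusion model in which evidence-accumulating agents' drift rates
    respond to the majority of already-decided group members, and a social
    reinforcement-learning model combining Rescorla-Wagner value updating
    with frequency-dependent (conformist) copying of other members' previous
    choices. Includes closed-form and numeric first-passage-time oracles,
    group simulators reproducing information cascades, self-organised
    decision order and maladaptive herding, maximum-likelihood fitting with
    a parameter-recovery harness, scenario generators, trace summaries and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
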