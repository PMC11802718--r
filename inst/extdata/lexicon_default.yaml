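# Default SUD category lexicon.
#
# One block per category: substance_terms (names/abbreviations of the
# substance), disorder_terms (phrases indicating a use disorder),
# severity_terms (DSM-5 severity specifiers and remission qualifiers), and
# proxy_ground_truth (canonical phrase used only to rank multiple surviving
# candidate answers in embedding space).
#
# All terms must be lowercase; matching is plain substring matching on
# lowercased, whitespace-collapsed text. disorder_terms and severity_terms
# shared by all categories live under `defaults` and may be overridden or
# extended per category.

defaults:
  disorder_terms:
    - use disorder
    - use d/o
    - use do
    - dependence
    - disorder
    - abuse
    - ud
    - d/o
  severity_terms:
    - mild
    - moderate
    - mod
    - severe
    - sever
    - severity unspecified
    - unspecified
    - in remission
    - in early remission
    - in sustained remission
    - in full remission
    - continuous use

categories:
  alcohol:
    display_name: alcohol
    substance_terms: [alcohol, etoh]
    proxy_ground_truth: alcohol use disorder/dependence
  opioid:
    display_name: opioid
    substance_terms: [opioid, opiate, heroin, kratom, vicodin, oxycodone, morphine, fentanyl]
    proxy_ground_truth: opioid use disorder/dependence
  cannabis:
    display_name: cannabis
    substance_terms: [cannabis, marijuana, mj, thc]
    proxy_ground_truth: cannabis use disorder/dependence
  sedative_hypnotic_anxiolytic:
    display_name: sedative, hypnotic or anxiolytic
    substance_terms: [sedative, hypnotic, anxiolytic, benzodiazepine, xanax, valium, ephedrine]
    proxy_ground_truth: sedative use disorder/dependence
  cocaine:
    display_name: cocaine
    substance_terms: [cocaine, crack]
    proxy_ground_truth: cocaine use disorder/dependence
  amphetamine:
    display_name: amphetamine
    # bare "stimulant" is claimed by this category (DSM-5 stimulant use
    # disorder covers amphetamine-type substances)
    substance_terms: [amphetamine, methamphetamine, stimulant]
    proxy_ground_truth: amphetamine use disorder/dependence
  caffeine:
    display_name: caffeine
    substance_terms: [caffeine]
    proxy_ground_truth: caffeine use disorder/dependence
  hallucinogen:
    display_name: hallucinogen
    substance_terms: [hallucinogen, mdma, ecstasy, lsd, psilocybin, phencyclidine]
    proxy_ground_truth: hallucinogen use disorder/dependence
  nicotine:
    display_name: nicotine
    substance_terms: [nicotine, tobacco, cigarette]
    proxy_ground_truth: nicotine use disorder/dependence
  inhalant:
    display_name: inhalant
    substance_terms: [inhalant, nitrous oxide, solvent]
    proxy_ground_truth: inhalant use disorder/dependence
  other_psychoactive:
    display_name: other psychoactive substance
    substance_terms: [other psychoactive, other/unknown substance, unknown substance, coricidin, kava]
    proxy_ground_truth: other/unknown substance use disorder/dependence
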