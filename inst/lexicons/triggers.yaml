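# Trigger lexicons. Every set is matched case-insensitively against token
# surface forms and lemmas; multiword entries are matched as token sequences.
# Lists contain the triggers quoted in the main-text description of the method
# plus their common orthographic/inflectional variants; all sets are
# config-extensible (pass a modified file to exprel_config()).

# Head nouns that type a noun phrase as an expression phrase.
expression_nouns:
  [expression, expressions, over-expression, overexpression, under-expression,
   underexpression, level, levels, amount, amounts, abundance, concentration,
   concentrations]

# Scale indicators (Type A comparisons), by direction.
si_high:
  [higher, greater, increased, elevated, raised, upregulated, up-regulated,
   overexpressed, over-expressed]
si_low:
  [lower, smaller, less, decreased, reduced, diminished, downregulated,
   down-regulated, underexpressed, under-expressed]

# Level indicators (Type B), implicit-comparison class: these presuppose an
# unstated baseline ("overexpressed" makes no sense without one).
li_implicit_high:
  [overexpressed, over-expressed, upregulated, up-regulated, increased,
   elevated, higher, raised]
li_implicit_low:
  [underexpressed, under-expressed, downregulated, down-regulated, decreased,
   reduced, lower, diminished]

# Level indicators, plain class: state a level without implying a comparison.
li_plain_high:
  [high, abundant, strong]
li_plain_low:
  [low, weak, absent, undetectable]

# Entity separators. "after"/"following" are a documented miss of the method
# and are shipped as an opt-in extension (es_extension), off by default.
entity_separators:
  [than, compared, versus, vs, vs., relative]
es_extension:
  [after, following]

# Head nouns that type a noun phrase as a disease sample. Bare organ nouns are
# included: fixtures with CEs such as "normal ovaries"/"normal brain tissues"
# require them.
disease_sample_heads:
  [tissue, tissues, cell, cells, patient, patients, sample, samples, tumor,
   tumors, tumour, tumours, specimen, specimens, line, lines, individual,
   individuals, control, controls, subject, subjects, case, cases, serum,
   sera, plasma, blood, biopsy, biopsies, man, men, woman, women, ovary,
   ovaries, brain, lung, lungs, liver, breast, colon, kidney, stomach,
   prostate, group, groups, cohort, cohorts]

# Noun modifiers marking a compared entity as a control/normal baseline.
control_modifiers:
  [control, controls, normal, healthy, adjacent, non-cancerous, noncancerous,
   non-tumor, nontumor, non-tumour, nontumour, cancer-free, non-malignant,
   nonmalignant]

# Generic disease phrases that by themselves do not resolve to an ontology
# term and send disease extraction to abstract context.
generic_disease_phrases:
  [tumor, tumors, tumour, tumours, cancer, cancers, carcinoma, carcinomas,
   disease, diseases, neoplasm, neoplasms, malignancy, malignancies]

# Agent/purpose words licensing an investigation sentence.
agent_words: [we, author, authors, study, investigators, researchers]
purpose_words: [aim, aims, objective, objectives, purpose, goal, goals]

# Investigation-aim triggers (need an agent/purpose subject or passive voice).
investigation_triggers:
  [investigate, investigated, examine, examined, analyze, analyzed, analyse,
   analysed, evaluate, evaluated, study, studied, compare, compared]

# Experimental-setup triggers (passive, theme NP contains a count).
analyzed_triggers:
  [tested, enrolled, collected, analyzed, analysed, measured, explored,
   assessed, recruited]

# Observation predicates heading P3/Q2/Q3 constructions.
observation_verbs:
  [found, find, detect, detected, observe, observed, note, noted, show,
   showed, shown, demonstrate, demonstrated, reveal, revealed, present,
   presented, report, reported, exhibit, exhibited, display, displayed, see,
   seen, identify, identified]
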