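# Dependency patterns for Type B (expression-level) relations.
# Same format as type_a.yaml. The extractor sets the implicit-comparison flag
# from the LI's trigger class and picks the expressed location nearest the LI
# when several candidate nmod:in edges exist.

patterns:
  - name: q1_li_predicate
    family: Q1
    nodes:
      li: {pos: "^(V|JJ)", lexicon: li}
      ea: {}
      el: {}
    edges:
      - {from: li, to: ea, label: "^nsubj"}
      - {from: li, to: el, label: "^nmod:in$"}
    result: [li, ea, el]

  - name: q2_observation_predicate
    family: Q2
    nodes:
      pred: {pos: "^V", lexicon: observation_verbs}
      li: {lexicon: li}
      ea: {}
      el: {}
    edges:
      - {from: pred, to: ea, label: "^nsubj"}
      - {from: ea, to: li, label: "^amod$"}
      - {from: pred, to: el, label: "^nmod:in$"}
    result: [li, ea, el]

  - name: q3_agentive_subject
    family: Q3
    nodes:
      pred: {pos: "^V", lexicon: observation_verbs}
      agent: {lexicon: agent_words}
      li: {lexicon: li}
      ea: {}
      el: {}
    edges:
      - {from: pred, to: agent, label: "^nsubj$"}
      - {from: pred, to: ea, label: "^dobj$"}
      - {from: ea, to: li, label: "^amod$"}
      - {from: pred, to: el, label: "^nmod:in$"}
    result: [li, ea, el]
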