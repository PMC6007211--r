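# Dependency patterns for Type A (comparative) relations.
#
# Node constraints: pos/lemma/surface are regexes; lexicon names a trigger set
# (membership tested on lowercased surface or lemma). Edge constraints give a
# regex on the dependency label. Variable bindings are injective. CE ordering,
# entity-separator verification and locality tie-breaks are applied by the
# extractor after matching (see extract_type_a).
#
# ES-initial constructions ("Compared to X, ...", "In comparison to X, ...")
# need no dedicated pattern: the analyzer attaches the fronted ES phrase to the
# main predicate as nmod:es, so the geometries below cover them.

patterns:
  - name: p1_comparative_adjective_predicate
    family: P1
    nodes:
      si: {pos: "^JJR", lexicon: si}
      ca: {}
      ce1: {}
      ce2: {}
    edges:
      - {from: si, to: ca, label: "^nsubj"}
      - {from: si, to: ce1, label: "^nmod:(in|es)$"}
      - {from: si, to: ce2, label: "^nmod:(in|es)$"}
    result: [si, ca, ce1, ce2]

  - name: p1_ca_attached_ce
    family: P1
    nodes:
      si: {pos: "^JJR", lexicon: si}
      ca: {}
      ce1: {}
      ce2: {}
    edges:
      - {from: si, to: ca, label: "^nsubj"}
      - {from: ca, to: ce1, label: "^nmod:(in|es)$"}
      - {from: si, to: ce2, label: "^nmod:(in|es)$"}
    result: [si, ca, ce1, ce2]

  - name: p2_verbal_predicate
    family: P2
    nodes:
      si: {pos: "^V", lexicon: si}
      ca: {}
      ce1: {}
      ce2: {}
    edges:
      - {from: si, to: ca, label: "^nsubj"}
      - {from: si, to: ce1, label: "^nmod:(in|es)$"}
      - {from: si, to: ce2, label: "^nmod:(in|es)$"}
    result: [si, ca, ce1, ce2]

  - name: p2_ca_attached_ce
    family: P2
    nodes:
      si: {pos: "^V", lexicon: si}
      ca: {}
      ce1: {}
      ce2: {}
    edges:
      - {from: si, to: ca, label: "^nsubj"}
      - {from: ca, to: ce1, label: "^nmod:(in|es)$"}
      - {from: si, to: ce2, label: "^nmod:(in|es)$"}
    result: [si, ca, ce1, ce2]

  - name: p3_observation_predicate
    family: P3
    nodes:
      pred: {pos: "^V", lexicon: observation_verbs}
      si: {lexicon: si}
      ca: {}
      ce1: {}
      ce2: {}
    edges:
      - {from: pred, to: ca, label: "^nsubj"}
      - {from: ca, to: si, label: "^amod$"}
      - {from: pred, to: ce1, label: "^nmod:(in|es)$"}
      - {from: pred, to: ce2, label: "^nmod:(in|es)$"}
    result: [si, ca, ce1, ce2]

  - name: p5_ce_subject
    family: P5
    nodes:
      pred: {pos: "^V", lexicon: observation_verbs}
      si: {lexicon: si}
      ca: {}
      ce1: {}
      ce2: {}
    edges:
      - {from: pred, to: ce1, label: "^nsubj$"}
      - {from: pred, to: ca, label: "^dobj$"}
      - {from: ca, to: si, label: "^amod$"}
      - {from: pred, to: ce2, label: "^nmod:(in|es)$"}
    result: [si, ca, ce1, ce2]
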