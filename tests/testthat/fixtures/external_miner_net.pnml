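<?xml version="1.0" encoding="UTF-8"?>
<!-- synthetic reference fixture: a minimal externally-mined style
     place/transition net (ids and layout unlike the package writer) -->
<pnml xmlns="http://www.pnml.org/version-2009/grammar/pnml">
  <net id="extnet" type="http://www.pnml.org/version-2009/grammar/ptnet">
    <page id="pg0">
      <place id="n1">
        <name><text>start</text></name>
        <initialMarking><text>1</text></initialMarking>
      </place>
      <place id="n2"><name><text>between</text></name></place>
      <place id="n3"><name><text>end</text></name></place>
      <transition id="n4"><name><text>A</text></name></transition>
      <transition id="n5"><name><text>B</text></name></transition>
      <arc id="e1" source="n1" target="n4"/>
      <arc id="e2" source="n4" target="n2"/>
      <arc id="e3" source="n2" target="n5"/>
      <arc id="e4" source="n5" target="n3"/>
    </page>
  </net>
</pnml>
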