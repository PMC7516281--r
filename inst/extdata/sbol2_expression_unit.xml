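<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic SBOL2 RDF/XML fixture (constructed, not a community file):
     one ComponentDefinition with an unlinked SequenceAnnotation and one
     ModuleDefinition exposing the unit with direction "in". -->
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:sbol="http://sbols.org/v2#">
  <sbol:Sequence rdf:about="http://example.com/sbol2file/unit_seq/1">
    <sbol:displayId>unit_seq</sbol:displayId>
    <sbol:elements>TTGACAGCTAGCTCAGTCCTAGGTATAATGCTAGCAAAGAGGAGAAA</sbol:elements>
  </sbol:Sequence>
  <sbol:ComponentDefinition rdf:about="http://example.com/sbol2file/unit/1">
    <sbol:displayId>unit</sbol:displayId>
    <sbol:type rdf:resource="http://www.biopax.org/release/biopax-level3.owl#DnaRegion"/>
    <sbol:role rdf:resource="https://identifiers.org/SO:0000804"/>
    <sbol:sequence rdf:resource="http://example.com/sbol2file/unit_seq/1"/>
    <sbol:sequenceAnnotation>
      <sbol:SequenceAnnotation rdf:about="http://example.com/sbol2file/unit/1/anno_promoter">
        <sbol:displayId>anno_promoter</sbol:displayId>
        <sbol:role rdf:resource="https://identifiers.org/SO:0000167"/>
        <sbol:location>
          <sbol:Range rdf:about="http://example.com/sbol2file/unit/1/anno_promoter/range">
            <sbol:displayId>range</sbol:displayId>
            <sbol:start>1</sbol:start>
            <sbol:end>35</sbol:end>
            <sbol:orientation rdf:resource="http://sbols.org/v2#inline"/>
          </sbol:Range>
        </sbol:location>
      </sbol:SequenceAnnotation>
    </sbol:sequenceAnnotation>
  </sbol:ComponentDefinition>
  <sbol:ModuleDefinition rdf:about="http://example.com/sbol2file/circuit/1">
    <sbol:displayId>circuit</sbol:displayId>
    <sbol:functionalComponent>
      <sbol:FunctionalComponent rdf:about="http://example.com/sbol2file/circuit/1/fc_unit">
        <sbol:displayId>fc_unit</sbol:displayId>
        <sbol:definition rdf:resource="http://example.com/sbol2file/unit/1"/>
        <sbol:access rdf:resource="http://sbols.org/v2#public"/>
        <sbol:direction rdf:resource="http://sbols.org/v2#in"/>
      </sbol:FunctionalComponent>
    </sbol:functionalComponent>
  </sbol:ModuleDefinition>
</rdf:RDF>
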