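<?xml version="1.0" encoding="UTF-8"?>
<!-- Schema of the provflow account dialect: one document per workflow
     execution. Collections are entities whose size attribute exceeds 1. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">

  <xs:simpleType name="timestamp">
    <xs:restriction base="xs:string">
      <xs:pattern value="\d{4}-\d{2}-\d{2}(T\d{2}:\d{2}:\d{2})?"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="relationKind">
    <xs:restriction base="xs:string">
      <xs:enumeration value="used"/>
      <xs:enumeration value="wasGeneratedBy"/>
      <xs:enumeration value="wasAssociatedWith"/>
      <xs:enumeration value="wasDerivedFrom"/>
      <xs:enumeration value="memberOf"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="derivationType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="filtering"/>
      <xs:enumeration value="ordering"/>
      <xs:enumeration value="mixing"/>
      <xs:enumeration value="other"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:element name="account">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="description" type="xs:string"/>
        <xs:element name="notes" type="xs:string"/>
        <xs:element name="agents">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="agent" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="group" type="xs:string" minOccurs="0" maxOccurs="unbounded"/>
                  </xs:sequence>
                  <xs:attribute name="id" type="xs:string" use="required"/>
                  <xs:attribute name="name" type="xs:string" use="required"/>
                  <xs:attribute name="institution" type="xs:string"/>
                  <xs:attribute name="position" type="xs:string"/>
                  <xs:attribute name="function" type="xs:string"/>
                  <xs:attribute name="notes" type="xs:string"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="activities">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="activity" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="group" type="xs:string" minOccurs="0" maxOccurs="unbounded"/>
                  </xs:sequence>
                  <xs:attribute name="id" type="xs:string" use="required"/>
                  <xs:attribute name="name" type="xs:string" use="required"/>
                  <xs:attribute name="program" type="xs:string"/>
                  <xs:attribute name="program_version" type="xs:string"/>
                  <xs:attribute name="command_line" type="xs:string"/>
                  <xs:attribute name="function" type="xs:string"/>
                  <xs:attribute name="start_time" type="timestamp"/>
                  <xs:attribute name="end_time" type="timestamp"/>
                  <xs:attribute name="environment" type="xs:string"/>
                  <xs:attribute name="notes" type="xs:string"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="entities">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="entity" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="group" type="xs:string" minOccurs="0" maxOccurs="unbounded"/>
                  </xs:sequence>
                  <xs:attribute name="id" type="xs:string" use="required"/>
                  <xs:attribute name="name" type="xs:string" use="required"/>
                  <xs:attribute name="size" type="xs:positiveInteger"/>
                  <xs:attribute name="description" type="xs:string"/>
                  <xs:attribute name="location" type="xs:string"/>
                  <xs:attribute name="notes" type="xs:string"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="relations">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="relation" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="id" type="xs:string" use="required"/>
                  <xs:attribute name="kind" type="relationKind" use="required"/>
                  <xs:attribute name="source" type="xs:string" use="required"/>
                  <xs:attribute name="target" type="xs:string" use="required"/>
                  <xs:attribute name="role" type="xs:string"/>
                  <xs:attribute name="derivation_type" type="derivationType"/>
                  <xs:attribute name="auto_derived" type="xs:boolean" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="annotations">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="annotation" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:simpleContent>
                    <xs:extension base="xs:string">
                      <xs:attribute name="element" type="xs:string" use="required"/>
                      <xs:attribute name="key" type="xs:string" use="required"/>
                    </xs:extension>
                  </xs:simpleContent>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="id" type="xs:string" use="required"/>
      <xs:attribute name="name" type="xs:string" use="required"/>
      <xs:attribute name="location" type="xs:string"/>
      <xs:attribute name="execution_date" type="timestamp"/>
      <xs:attribute name="version_date" type="timestamp"/>
      <xs:attribute name="version" type="xs:positiveInteger" use="required"/>
      <xs:attribute name="start_time" type="timestamp"/>
      <xs:attribute name="end_time" type="timestamp"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
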