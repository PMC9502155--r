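# Simplified CEF feature dialect

The package reads and writes a minimal subset of the CEF XML feature
format, sufficient to carry m/z, drift (arrival) time and intensity.
Full vendor CEF is out of scope; this schema is the normative contract
for `read_features_cef()` / `write_features_cef()`.

```
<CEF version="1.0">
  <CompoundList>            <!-- zero or more Compound elements -->
    <Compound>
      <Location m="322.0481"   <!-- m/z (Th), required, > 0 -->
                dt="25.31"     <!-- drift/arrival time (ms), required, > 0 -->
                y="120000"/>   <!-- intensity (counts), optional, >= 0;
                                    missing treated as 0 -->
    </Compound>
  </CompoundList>
</CEF>
```

Rules:

* exactly one `Location` per `Compound`; a `Compound` without one is a
  schema error;
* a missing `m` or `dt` attribute is a schema error;
* an empty `CompoundList` is valid and yields an empty feature table;
* numbers use a period decimal separator (locale-independent).
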