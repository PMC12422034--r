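country,profile,integrated,standard,printed_difference
Uganda,HIV,668995477,698801557,-29806079
Uganda,HTN,347416601,354755964,-7339363
Uganda,DM,61292465,51949839,9342627
Uganda,HIV+HTN,139322728,207122763,-67800034
Uganda,HIV+DM,17929185,22435573,-4506389
Uganda,HTN+DM,148242221,258103172,-109860952
Uganda,HIV+HTN+DM,28812121,47366642,-18554521
Tanzania,HIV,744234202,738480466,5753736
Tanzania,HTN,140432057,124044720,16387337
Tanzania,DM,169257387,143454269,25803119
Tanzania,HIV+HTN,157440559,183461692,-26021133
Tanzania,HIV+DM,30088514,34742322,-4653808
Tanzania,HTN+DM,275251488,355161469,-79909981
Tanzania,HIV+HTN+DM,33546797,42952128,-9405330
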