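# Template category definitions: 25 mutually exclusive, health-relevant
# business categories (food environment, alcohol outlets, physical
# activity venues, medical facilities, destinations of daily living).
#
# The SIC sets, name patterns and size thresholds below are ILLUSTRATIVE,
# not canonical: real research definitions are developed iteratively with
# manual SIC review and are study-specific. Edit freely. "5812*" means
# any 8-digit SIC starting 5812; bare codes match exactly.
#
# priority resolves multi-category matches (lowest rank wins), so
# size-restricted definitions (Large supermarket) rank above the residual
# categories they carve out of (Convenience store or small grocery
# store), and name-driven definitions (Multi-use physical activity venue)
# rank above SIC-driven physical-activity categories.
categories:
  - name: Large supermarket
    priority: 1
    sic: ["5411*"]
    min_employees: 50
    min_sales: 2000000
  - name: Multi-use physical activity venue
    priority: 2
    sic: ["79910000"]
    name_include: ["\\bYMCA\\b", "\\bYWCA\\b", "\\bJCC\\b",
                   "JEWISH COMMUNITY CENTER"]
  - name: Vigorous physical activity venue
    priority: 3
    sic: ["79910100", "79970100", "79970200", "7999490*"]
    met_value: 8.0
  - name: Light/moderate physical activity venue
    priority: 4
    sic: ["7933*", "79920000", "79970300", "7999170*"]
    met_value: 3.5
  - name: Fast food restaurant
    priority: 5
    sic: ["58120300", "58120700"]
    name_exclude: ["PIZZA"]
  - name: Pizza restaurant
    priority: 6
    sic: ["58120500"]
    name_include: ["PIZZA", "PIZZERIA"]
  - name: Other restaurant—not fast food, not pizza
    priority: 7
    sic: ["5812*"]
  - name: Bar or other public drinking place
    priority: 8
    sic: ["5813*"]
  - name: Liquor store
    priority: 9
    sic: ["5921*"]
  - name: Fish market
    priority: 10
    sic: ["54210200"]
  - name: Meat market
    priority: 11
    sic: ["54210100"]
  - name: Fruit and vegetable market
    priority: 12
    sic: ["5431*"]
  - name: Natural food market or nut store
    priority: 13
    sic: ["5499*"]
  - name: Bakery or candy/confectionary store
    priority: 14
    sic: ["5461*", "5441*"]
  - name: Warehouse or discount department store selling food
    priority: 15
    sic: ["53110100", "53310100"]
    min_sales: 5000000
  - name: Convenience store or small grocery store
    priority: 16
    sic: ["5411*"]
  - name: Urgent care or hospital facility
    priority: 17
    sic: ["8062*", "80110300"]
  - name: Office or clinic of health practitioner
    priority: 18
    sic: ["8011*", "8041*", "8042*", "8043*", "8049*"]
  - name: Dental care
    priority: 19
    sic: ["8021*"]
  - name: Mental health care
    priority: 20
    sic: ["8063*", "80490300", "8093*"]
  - name: Residential facility with health care
    priority: 21
    sic: ["8051*", "8052*", "8059*"]
  - name: Pharmacy
    priority: 22
    sic: ["5912*"]
  - name: Bank
    priority: 23
    sic: ["6021*", "6022*", "6029*"]
  - name: Credit union
    priority: 24
    sic: ["6061*", "6062*"]
  - name: Other potential destination
    priority: 25
    sic: ["5942*", "7832*", "8412*", "79990101"]
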