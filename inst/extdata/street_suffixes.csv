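abbrev,full
ST,STREET
AVE,AVENUE
BLVD,BOULEVARD
RD,ROAD
DR,DRIVE
LN,LANE
CT,COURT
PL,PLACE
TER,TERRACE
PKWY,PARKWAY
HWY,HIGHWAY
EXPY,EXPRESSWAY
SQ,SQUARE
CIR,CIRCLE
ALY,ALLEY
BND,BEND
BR,BRANCH
BRG,BRIDGE
BYP,BYPASS
CSWY,CAUSEWAY
CTR,CENTER
CLF,CLIFF
CMN,COMMON
COR,CORNER
CRES,CRESCENT
XING,CROSSING
DL,DALE
DM,DAM
EST,ESTATE
FLD,FIELD
FRD,FORD
FRST,FOREST
GDN,GARDEN
GLN,GLEN
GRN,GREEN
GRV,GROVE
HBR,HARBOR
HTS,HEIGHTS
HL,HILL
IS,ISLAND
JCT,JUNCTION
LNDG,LANDING
MDW,MEADOW
ML,MILL
MT,MOUNT
ORCH,ORCHARD
PT,POINT
RDG,RIDGE
ROW,ROW
RTE,ROUTE
SHR,SHORE
SPG,SPRING
STA,STATION
TRL,TRAIL
TPKE,TURNPIKE
VLG,VILLAGE
VW,VIEW
WAY,WAY
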